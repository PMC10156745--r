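# Contact graph, patch detection, PCP score, mutation scanning.

random_fixture <- function(seed, n_patches = NULL) {
  set.seed(seed)
  k <- if (is.null(n_patches)) sample(1:3, 1) else n_patches
  generate_shell_structure(
    patch_spec(sizes = sort(sample(3:8, k, replace = TRUE),
                            decreasing = TRUE),
               shell_radius = sample(12:16, 1), n_buried = 0,
               seed = seed))
}

test_that("contact graph equals a brute-force distance scan", {
  for (seed in 1:12) {
    p <- fixture_pipeline(random_fixture(seed))
    oracle <- oracle_contact_edges(p$s, p$g$nodes, cutoff = 5)
    expect_identical(canon_edges(p$g$edges), canon_edges(oracle))
  }
})

test_that("residues far apart share no edge; cutoff must be positive", {
  f <- tempfile(fileext = ".pdb")
  write_mini_pdb(f, resno = 1:2, resid = "LYS", x = c(0, 100), y = 0,
                 z = 0)
  s <- assign_charges(parse_structure(f))
  ann <- classify_surface(compute_sasa(s),
                          max_asa_table = max_asa_sphere())
  g <- build_contact_graph(s, ann, cutoff = 5)
  expect_equal(nrow(g$edges), 0)
  expect_error(build_contact_graph(s, ann, cutoff = 0), "cutoff")
})

test_that("contact graph is invariant under rigid-body transforms", {
  p <- fixture_pipeline(random_fixture(31))
  s2 <- transform_structure(p$s, rotation_matrix(c(0, 1, 1), 2.2),
                            shift = c(-4, 9, 17))
  g2 <- build_contact_graph(s2, p$ann, cutoff = 5)
  expect_identical(canon_edges(p$g$edges), canon_edges(g2$edges))
})

test_that("patch partition equals brute-force flood fill", {
  for (seed in 13:24) {
    p <- fixture_pipeline(random_fixture(seed))
    ps <- find_patches(p$g, p$s, sign = +1)
    # oracle: flood fill over the positive-node induced subgraph
    q <- p$s$residues$charge[match(p$g$node_index,
                                   p$s$residues$res_index)]
    pos <- which(q > 0)
    sub <- p$g$edges[p$g$edges[, 1] %in% pos & p$g$edges[, 2] %in% pos, ,
                     drop = FALSE]
    sub <- cbind(match(sub[, 1], pos), match(sub[, 2], pos))
    comp <- oracle_components(length(pos), sub)
    got <- lapply(ps$patches, function(pp)
      sort(match(match(pp$members, p$s$residues$res_key),
                 p$g$node_index)))
    want <- lapply(canon_partition(comp), function(m) sort(pos[m]))
    expect_setequal(got, want)
    expect_equal(sort(ps$sizes, decreasing = TRUE), ps$sizes)
  }
})

test_that("planted patch sizes are recovered exactly", {
  fix <- generate_shell_structure(patch_spec(sizes = c(12, 9, 5),
                                             seed = 7))
  p <- fixture_pipeline(fix, run_sasa = TRUE)
  ps <- find_patches(p$g, p$s, sign = +1)
  expect_identical(ps$sizes, c(12L, 9L, 5L))
  expect_equal(ps$pcp_score, 26L)
  # membership matches the manifest patch labels
  planted <- split(fix$manifest$res_key[fix$manifest$patch > 0],
                   fix$manifest$patch[fix$manifest$patch > 0])
  got <- lapply(ps$patches, function(pp) sort(pp$members))
  expect_setequal(got, lapply(planted, sort))
})

test_that("PCP score sums the top three patch sizes", {
  mk <- function(sizes) structure(list(sizes = as.integer(sizes)),
                                  class = "patch_set")
  expect_equal(pcp_score(mk(c(20, 15, 10, 5))), 45L)
  expect_equal(pcp_score(mk(7)), 7L)
  expect_equal(pcp_score(mk(integer(0))), 0L)
})

test_that("a structure without positive surface residues scores zero", {
  f <- tempfile(fileext = ".pdb")
  write_mini_pdb(f, resno = 1:4, resid = c("GLY", "ASP", "GLU", "SER"),
                 x = c(0, 4, 8, 12), y = 0, z = 0)
  s <- assign_charges(parse_structure(f))
  ann <- classify_surface(compute_sasa(s),
                          max_asa_table = max_asa_sphere())
  g <- build_contact_graph(s, ann, cutoff = 5)
  ps <- find_patches(g, s, sign = +1)
  expect_length(ps$patches, 0)
  expect_equal(ps$pcp_score, 0L)
  # the same machinery finds the negative patch
  neg <- find_patches(g, s, sign = -1)
  expect_equal(neg$sizes, 2L)
})

test_that("ties rank by smallest chain/residue number", {
  # two patches of equal size on one line, separated by a gap
  f <- tempfile(fileext = ".pdb")
  write_mini_pdb(f, resno = 1:5,
                 resid = c("LYS", "LYS", "GLY", "LYS", "LYS"),
                 x = c(0, 4, 50, 100, 104), y = 0, z = 0)
  s <- assign_charges(parse_structure(f))
  ann <- classify_surface(compute_sasa(s),
                          max_asa_table = max_asa_sphere())
  ps <- find_patches(build_contact_graph(s, ann, 5), s)
  expect_equal(ps$sizes, c(2L, 2L))
  expect_equal(ps$patches[[1]]$members, c("A:1", "A:2"))
  expect_equal(ps$patches[[2]]$members, c("A:4", "A:5"))
})

test_that("patch-set serialization is deterministic", {
  p1 <- fixture_pipeline(random_fixture(40))
  p2 <- fixture_pipeline(random_fixture(40))
  j1 <- patchset_json(find_patches(p1$g, p1$s))
  j2 <- patchset_json(find_patches(p2$g, p2$s))
  expect_identical(as.character(j1), as.character(j2))
})

test_that("neutralizing every positive residue zeroes the score", {
  p <- fixture_pipeline(random_fixture(50), run_sasa = TRUE)
  pos <- p$s$residues$res_key[!is.na(p$s$residues$charge) &
                                p$s$residues$charge > 0]
  cand <- data.frame(res_key = pos, new_type = "SER",
                     stringsAsFactors = FALSE)
  res <- mutation_scan(p$s, p$ann, cand, direction = "down",
                       graph = p$g, combinatorial = TRUE)
  expect_equal(res$pcp_score, 0L)
  expect_equal(res$delta_pcp, -attr(res, "base_score"))
})

test_that("mutating a buried residue never changes the score", {
  fix <- generate_shell_structure(patch_spec(sizes = c(6, 4),
                                             shell_radius = 13,
                                             n_buried = 20, seed = 3))
  p <- fixture_pipeline(fix, run_sasa = TRUE)
  buried <- fix$manifest$res_key[!fix$manifest$surface]
  cand <- data.frame(res_key = buried[1:5], new_type = "LYS",
                     stringsAsFactors = FALSE)
  res <- mutation_scan(p$s, p$ann, cand, direction = "up", graph = p$g)
  expect_true(all(res$delta_pcp == 0))
})

test_that("scan ranking equals exhaustive recomputation", {
  p <- fixture_pipeline(random_fixture(60, n_patches = 3),
                        run_sasa = TRUE)
  pos <- p$s$residues$res_key[!is.na(p$s$residues$charge) &
                                p$s$residues$charge > 0]
  cand <- data.frame(res_key = pos, new_type = "ALA",
                     stringsAsFactors = FALSE)
  res <- mutation_scan(p$s, p$ann, cand, direction = "down",
                       graph = p$g)
  # oracle: recompute each mutant score independently
  for (i in seq_len(nrow(res))) {
    s2 <- p$s
    k <- match(res$res_key[i], s2$residues$res_key)
    s2$residues$charge[k] <- 0
    s2$residues$resid[k] <- "ALA"
    expect_equal(res$pcp_score[i],
                 find_patches(p$g, s2, sign = +1)$pcp_score)
  }
  expect_true(all(diff(abs(res$delta_pcp)) <= 0))
})

test_that("scan rejects unknown and CDR-masked positions", {
  p <- fixture_pipeline(random_fixture(70), run_sasa = TRUE)
  bad <- data.frame(res_key = "Z:999", new_type = "LYS")
  expect_error(mutation_scan(p$s, p$ann, bad, graph = p$g), "unknown")
  pos <- p$s$residues$res_key[1]
  cand <- data.frame(res_key = pos, new_type = "SER")
  expect_error(mutation_scan(p$s, p$ann, cand, graph = p$g,
                             cdr_mask = pos), "CDR")
})

test_that("charge-down moves never increase the score (monotonicity)", {
  p <- fixture_pipeline(random_fixture(80, n_patches = 3),
                        run_sasa = TRUE)
  base <- find_patches(p$g, p$s)
  pos_keys <- p$s$residues$res_key[!is.na(p$s$residues$charge) &
                                     p$s$residues$charge > 0]
  set.seed(81)
  for (k in sample(pos_keys, min(30, length(pos_keys)))) {
    s2 <- p$s
    s2$residues$charge[s2$residues$res_key == k] <- 0
    ps2 <- find_patches(p$g, s2)
    expect_lte(ps2$pcp_score, base$pcp_score)
    # multiset domination: sorted sizes never exceed the originals
    a <- sort(ps2$sizes, decreasing = TRUE)
    b <- sort(base$sizes, decreasing = TRUE)
    b <- c(b, rep(0L, max(0, length(a) - length(b))))
    expect_true(all(cumsum(a) <= cumsum(b)[seq_along(a)]))
  }
})

test_that("charging a residue adjacent to two patches merges them", {
  # linear chain: K K . gap-bridging glycine . K  (distances 4 apart)
  f <- tempfile(fileext = ".pdb")
  write_mini_pdb(f, resno = 1:5,
                 resid = c("LYS", "LYS", "GLY", "LYS", "LYS"),
                 x = c(0, 4, 8, 12, 16), y = 0, z = 0)
  s <- assign_charges(parse_structure(f))
  ann <- classify_surface(compute_sasa(s),
                          max_asa_table = max_asa_sphere())
  g <- build_contact_graph(s, ann, 5)
  before <- find_patches(g, s)
  expect_equal(before$sizes, c(2L, 2L))
  s$residues$charge[3] <- 1
  after <- find_patches(g, s)
  expect_equal(after$sizes, 5L)            # size1 + size2 + 1
})

test_that("mutation specs parse and reject malformed lines", {
  m <- parse_mutations(c("A:42:S", "B:7:LYS", "# comment", ""))
  expect_equal(m$res_key, c("A:42", "B:7"))
  expect_equal(m$new_type, c("SER", "LYS"))
  expect_error(parse_mutations("A42S"), "malformed")
  expect_error(parse_mutations("A:42:J"), "unknown residue")
})
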