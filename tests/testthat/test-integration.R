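test_that("apoptosis universe is map-then-subtract", {
  u <- build_apoptosis_universe(c("a", "b", "c"), c("b"))
  expect_setequal(u$members, c("A", "C"))

  expect_warning(u0 <- build_apoptosis_universe(c("a"), c("a", "b")), "empty")
  expect_length(u0$members, 0)

  # ortholog mapping: one-to-many expands, unmapped dropped
  map <- data.frame(from = c("m1", "m1", "m2", "m3"),
                    to = c("H1A", "H1B", "H2", "H3"))
  expect_message(
    u2 <- build_apoptosis_universe(c("m1", "m2", "mX"), c("m3"),
                                   ortholog_map = map),
    "without ortholog")
  expect_setequal(u2$members, c("H1A", "H1B", "H2"))

  # brute-force oracle
  set.seed(21)
  a <- sample(paste0("m", 1:50), 30)
  n <- sample(paste0("m", 1:50), 15)
  map2 <- data.frame(from = paste0("m", 1:40), to = paste0("H", 1:40))
  u3 <- suppressMessages(build_apoptosis_universe(a, n, map2))
  fromU <- toupper(map2$from)
  toU <- toupper(map2$to)
  brute <- setdiff(toU[fromU %in% toupper(a)], toU[fromU %in% toupper(n)])
  expect_setequal(u3$members, brute)

  expect_error(build_apoptosis_universe(character(0), "x"), "nonempty")
})

test_that("invasiveness universe is a normalised union", {
  u <- build_invasiveness_universe(c("a"), c("b"), c("c"))
  expect_setequal(u$members, c("A", "B", "C"))
  expect_setequal(build_invasiveness_universe(c("a", "b"), c("b", "c"))$members,
                  c("A", "B", "C"))
  set.seed(22)
  s1 <- sample(letters, 10); s2 <- sample(letters, 10); s3 <- sample(letters, 5)
  expect_setequal(build_invasiveness_universe(s1, s2, s3)$members,
                  unique(toupper(c(s1, s2, s3))))
  expect_error(build_invasiveness_universe(character(0)), "nonempty")
})

test_that("venn_partition enumerates disjoint exhaustive patterns", {
  v <- venn_partition(list(A = c("1", "2"), B = c("2", "3")))
  expect_equal(v$patterns[["A"]], "1")
  expect_equal(v$patterns[["B"]], "3")
  expect_equal(v$patterns[["A&B"]], "2")

  same <- venn_partition(list(A = c("x", "y"), B = c("x", "y")))
  expect_length(same$patterns[["A"]], 0)
  expect_setequal(same$patterns[["A&B"]], c("X", "Y"))

  # 4 random sets vs brute-force membership enumeration
  set.seed(23)
  sets <- lapply(setNames(1:4, c("A", "B", "C", "D")), function(i) {
    sample(sprintf("g%03d", 1:120), 50)
  })
  v4 <- venn_partition(sets)
  univ <- unique(toupper(unlist(sets)))
  brute <- split(univ, vapply(univ, function(g) {
    paste(names(sets)[vapply(sets, function(s) g %in% toupper(s),
                             logical(1))], collapse = "&")
  }, character(1)))
  for (key in names(brute)) {
    expect_setequal(v4$patterns[[key]], brute[[key]])
  }
  # disjoint and exhaustive
  expect_equal(sum(v4$counts), length(univ))
  expect_false(anyDuplicated(unlist(v4$patterns)) > 0)

  expect_error(venn_partition(list(a = "x")), "2-5 sets")
  expect_error(venn_partition(rep(list(letters), 6)), "2-5 sets")
})

test_that("signature assembly takes exactly the four patterns of interest", {
  # construct inputs whose four target Venn regions have sizes 2, 8, 21, 11
  core <- c("GADD45B", "UBE4B")
  s_b_p <- sprintf("BP%02d", 1:8)    # lineB & peaks & apoptosis only
  s_a_p <- sprintf("AP%02d", 1:21)   # lineA & peaks & apoptosis only
  s_a_b <- sprintf("AB%02d", 1:11)   # lineA & lineB & apoptosis only
  extra <- c("XA1", "XB1", "XP1", "XAPO1")  # padding outside the patterns
  deg_a <- c(core, s_a_p, s_a_b, "XA1", "XP0")
  deg_b <- c(core, s_b_p, s_a_b, "XB1", "XP0")
  peaks <- c(core, s_a_p, s_b_p, "XP1")
  apopt <- c(core, s_a_p, s_b_p, s_a_b, "XAPO1")
  v <- venn_partition(list(DEG_A = deg_a, DEG_B = deg_b, Peaks = peaks,
                           Apoptosis = apopt))
  sig <- assemble_apoptosis_signature(v, deg_a = "DEG_A", deg_b = "DEG_B",
                                      peak_genes = "Peaks",
                                      apoptosis = "Apoptosis")
  expect_length(sig$members, 42)
  expect_setequal(sig$members[sig$provenance == "core_all_four"], core)
  expect_equal(sum(sig$provenance == "lineB_peaks_apoptosis"), 8)
  expect_equal(sum(sig$provenance == "lineA_peaks_apoptosis"), 21)
  expect_equal(sum(sig$provenance == "lineA_lineB_apoptosis"), 11)

  # all four sets equal -> signature = common set, tagged all-four
  s <- c("G1", "G2")
  v2 <- venn_partition(list(A = s, B = s, P = s, U = s))
  sig2 <- assemble_apoptosis_signature(v2, "A", "B", "P", "U")
  expect_setequal(sig2$members, s)
  expect_true(all(sig2$provenance == "core_all_four"))

  # brute-force evaluation of the set expression on raw inputs
  brute <- unique(c(
    Reduce(intersect, list(deg_a, deg_b, peaks, apopt)),
    setdiff(Reduce(intersect, list(deg_b, peaks, apopt)), deg_a),
    setdiff(Reduce(intersect, list(deg_a, peaks, apopt)), deg_b),
    setdiff(Reduce(intersect, list(deg_a, deg_b, apopt)), peaks)))
  expect_setequal(sig$members, toupper(brute))

  expect_error(assemble_apoptosis_signature(v, "DEG_A", "DEG_B", "Peaks",
                                            "Missing"), "four named sets")
})

test_that("baseline marker screen flags by strict thresholds", {
  set.seed(24)
  n <- 20
  expr <- matrix(2^rnorm(50 * 2 * n, mean = 5, sd = 0.3), nrow = 50)
  rownames(expr) <- sprintf("g%02d", 1:50)
  groups <- rep(c("sensitive", "resistant"), each = n)

  # identical groups -> nothing flagged
  sym <- cbind(expr[, 1:n], expr[, 1:n])
  r0 <- baseline_marker_screen(sym, groups)
  expect_false(any(r0$flagged))

  # one gene shifted by 1 log2 unit: flagged up in sensitive
  shifted <- expr
  shifted[1, 1:n] <- shifted[1, 1:n] * 2
  r1 <- baseline_marker_screen(shifted, groups)
  expect_true(r1$flagged[1])
  expect_equal(r1$direction[1], "up_in_sensitive")

  # |lfc| exactly at the threshold is NOT flagged (strict inequality)
  x <- matrix(0, nrow = 1, ncol = 8)
  x[1, ] <- c(1.0, 2.0, 1.5, 2.5, 0.7, 1.7, 1.2, 2.2)  # diff exactly 0.3
  rb <- baseline_marker_screen(x, rep(c("sensitive", "resistant"), each = 4),
                               log_input = TRUE)
  expect_equal(rb$lfc, 0.3)
  expect_false(rb$flagged)

  expect_error(baseline_marker_screen(expr[, 1:3],
                                      c("sensitive", "resistant",
                                        "resistant")), ">= 2")
})
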