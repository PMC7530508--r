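test_that("golden split puts N/C segment lengths in the golden ratio", {
  expect_equal(golden_split(10, 1),
               matrix(c(0L, 6L, 6L, 10L), 2, 2, byrow = TRUE,
                      dimnames = list(c("N", "C"), c("start", "end"))))
  expect_equal(unname(golden_split(2, 1)),
               matrix(c(0L, 1L, 1L, 2L), 2, 2, byrow = TRUE))
  # Fibonacci-adjacent length: 13 splits as 8 + 5
  expect_equal(unname(golden_split(13, 1)[, "end"]), c(8L, 13L))
})

test_that("golden split segments are contiguous, non-overlapping and cover [0, L)", {
  for (L in c(12, 20, 57, 301)) {
    for (depth in 1:3) {
      seg <- golden_split(L, depth)
      expect_equal(nrow(seg), 2^depth)
      expect_equal(seg[1, "start"], 0L)
      expect_equal(seg[nrow(seg), "end"], as.integer(L))
      expect_true(all(seg[-1, "start"] == seg[-nrow(seg), "end"]))
      expect_true(all(seg[, "end"] > seg[, "start"]))
    }
  }
})

test_that("too-short sequences for the requested depth error with the minimum", {
  expect_error(golden_split(1, 1), "minimum length is 2")
  # depth 3 needs more than 2^3 residues because the split is uneven
  expect_error(golden_split(8, 3), "minimum length")
})

test_that("SAAC counts residue frequencies per golden segment", {
  v <- encode_saac("AAAAAACCCC", depth = 1)
  expect_length(v, 40)
  expect_equal(unname(v["SAAC_N_A"]), 1)
  expect_equal(unname(v["SAAC_C_C"]), 1)
  expect_equal(sum(v), 2)  # each segment sums to 1
  v2 <- encode_saac(rand_seq(50), depth = 2)
  expect_length(v2, 80)
  expect_identical(unique(sub("^SAAC_([A-Z]+)_.*$", "\\1", names(v2))),
                   c("NN", "NC", "CN", "CC"))
  sums <- tapply(v2, sub("^SAAC_([A-Z]+)_.*$", "\\1", names(v2)), sum)
  expect_equal(as.numeric(sums), rep(1, 4), tolerance = 1e-12)
})

test_that("DC matches hand counts and normalises over L - 1 pairs", {
  v <- encode_dc("ACAC")
  expect_length(v, 400)
  expect_equal(unname(v["DC_AC"]), 2 / 3)
  expect_equal(unname(v["DC_CA"]), 1 / 3)
  expect_equal(sum(v), 1)
  expect_equal(unname(encode_dc("AA")["DC_AA"]), 1)
  expect_error(encode_dc("A"), ">= 2")
})

test_that("the conjoint-triad alphabet maps residues to the 7 groups", {
  expect_identical(residue_group(c("A", "G", "V")), c(1L, 1L, 1L))
  expect_identical(residue_group(c("R", "K")), c(5L, 5L))
  expect_identical(residue_group("C"), 7L)
  expect_identical(sort(unique(residue_group(AA_ALPHABET20))), 1:7)
  expect_error(residue_group("X"), "unknown")
})

test_that("CTF counts group triads over sliding windows", {
  v <- encode_ctf("AGV")
  expect_length(v, 343)
  expect_equal(unname(v["CTF_1_1_1"]), 1)
  expect_equal(sum(v), 1)
  v2 <- encode_ctf("AGVIL")
  expect_equal(unname(v2[c("CTF_1_1_1", "CTF_1_1_2", "CTF_1_2_2")]),
               rep(1 / 3, 3))
  expect_error(encode_ctf("AG"), ">= 3")
})

test_that("DC and CTF agree exactly with naive counting oracles", {
  set.seed(7)
  for (i in 1:200) {
    s <- rand_seq(sample(3:80, 1))
    expect_equal(encode_dc(s), naive_dc(s), tolerance = 0)
    expect_equal(encode_ctf(s), naive_ctf(s), tolerance = 0)
  }
})

test_that("PseACS reproduces closed-form lag features", {
  # homopolymer: all shifts equal, every lag feature vanishes
  tab <- toy_acs_table(stats::setNames(seq(1, 20), AA_ALPHABET20))
  v <- encode_pseacs(strrep("A", 60), tab, lambda = 5)
  expect_equal(unname(v[grepl("lag[1-5]$", names(v))]), rep(0, 20))
  # alternating two-valued series: phi(odd) = squared gap, phi(even) = 0
  tab2 <- toy_acs_table(stats::setNames(c(1, rep(3, 19)),
                                        c("A", setdiff(AA_ALPHABET20, "A"))))
  s <- paste(rep(c("A", "G"), 28), collapse = "")  # L = 56
  v2 <- encode_pseacs(s, tab2, lambda = 2)
  for (nuc in ACS_NUCLEI) {
    expect_equal(unname(v2[paste0("PseACS_", nuc, "_lag1")]), 4)
    expect_equal(unname(v2[paste0("PseACS_", nuc, "_lag2")]), 0)
  }
})

test_that("PseACS dimension, lag-0 modes and length preconditions hold", {
  s <- rand_seq(60)
  v <- encode_pseacs(s)
  expect_length(v, 220)  # 4 nuclei x (54 + 1) lags
  expect_equal(unname(v[grepl("lag0$", names(v))]), rep(0, 4))
  vm <- encode_pseacs(s, lambda = 3, tier0 = "mean")
  tab <- default_acs_table()
  idx <- match(strsplit(s, "")[[1]], AA_ALPHABET20)
  expect_equal(unname(vm["PseACS_N15_lag0"]),
               mean(unclass(tab)[idx, "N15"]))
  expect_error(encode_pseacs(rand_seq(54), lambda = 54), "length > 54")
})

test_that("PseACS is invariant to a constant offset of the ACS table", {
  set.seed(11)
  s <- rand_seq(70)
  base <- default_acs_table()
  shifted <- acs_table(unclass(base) + 100)
  a <- encode_pseacs(s, base, lambda = 10)
  b <- encode_pseacs(s, shifted, lambda = 10)
  lags <- grepl("lag([1-9]|10)$", names(a))
  expect_equal(a[lags], b[lags], tolerance = 1e-9)
})

test_that("combined encoding concatenates named blocks in fixed order", {
  s <- rand_seq(80)
  v <- encode_combined(s)
  expect_length(v, 1003)
  bi <- attr(v, "block_index")
  expect_identical(bi$block, c("SAAC", "DC", "CTF", "PSEACS"))
  expect_identical(bi$length, c(40L, 400L, 343L, 220L))
  expect_equal(sum(bi$length), length(v))
  # single-block identity
  expect_equal(as.numeric(encode_combined(s, encoders = "dc")),
               as.numeric(encode_dc(s)))
  # precondition failures name the offending block
  expect_error(encode_combined(rand_seq(50)), "PSEACS")
})

test_that("adjacency-sensitive encoders distinguish shuffled sequences", {
  set.seed(3)
  s <- paste(rep(c("A", "C", "D"), 40), collapse = "")  # strong adjacency
  chars <- strsplit(s, "")[[1]]
  shuf <- paste(sample(chars), collapse = "")
  expect_gt(sum(abs(encode_dc(s) - encode_dc(shuf))), 0)
  expect_gt(sum(abs(encode_ctf(s) - encode_ctf(shuf))), 0)
  expect_gt(sum(abs(encode_pseacs(s, lambda = 5) -
                    encode_pseacs(shuf, lambda = 5))), 0)
  # SAAC depth 1 only sees composition per segment
  seg <- golden_split(nchar(s), 1)
  within <- paste(c(sample(chars[1:seg["N", "end"]]),
                    sample(chars[(seg["N", "end"] + 1):length(chars)])),
                  collapse = "")
  expect_equal(encode_saac(s), encode_saac(within))
})

test_that("dataset encoding yields a named matrix with block metadata", {
  d <- simulate_dataset(sim_config(class_sizes = c(4, 6),
                                   length_range = c(60, 90), seed = 5))
  X <- encode_dataset(d, encoders = c("saac", "dc"))
  expect_equal(dim(X), c(10L, 440L))
  expect_identical(rownames(X), names(d$records))
  expect_true(all(grepl("^(SAAC|DC)_", colnames(X))))
  expect_error(encode_dataset(structure(c(bad = "ACDE"),
                                        class = "protein_records"),
                              encoders = "pseacs"),
               "bad")
})
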