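# A hand-built fragment table: helper to lay out one peptide's fragments
# across samples from a matrix of intensities (rows fragments, cols samples).
toy_fragments <- function(peptides, control = "CTRL") {
  rows <- list()
  meta <- list()
  for (pep in names(peptides)) {
    spec <- peptides[[pep]]
    m <- spec$m
    for (fi in seq_len(nrow(m))) {
      rows[[length(rows) + 1]] <- data.frame(
        peptide_id = pep, fragment_id = paste0(pep, "_f", fi),
        sample = colnames(m), condition = sub("_R[0-9]+$", "", colnames(m)),
        replicate = as.integer(sub("^.*_R", "", colnames(m))),
        intensity = m[fi, ], stringsAsFactors = FALSE)
    }
    meta[[length(meta) + 1]] <- data.frame(
      peptide_id = pep, protein = spec$protein, sequence = spec$sequence,
      offsets = spec$offsets, stringsAsFactors = FALSE)
  }
  fragment_table(do.call(rbind, rows), do.call(rbind, meta), control = control)
}

samples6 <- c("CTRL_R1", "CTRL_R2", "CTRL_R3", "TRT_R1", "TRT_R2", "TRT_R3")

test_that("intensity filter boundary is strict at 2000", {
  m <- matrix(c(1999, 2001, 2000, 2001, 2001, 2001,
                5000, 5000, 5000, 5000, 5000, 5000),
              nrow = 2, byrow = TRUE, dimnames = list(NULL, samples6))
  t <- toy_fragments(list(p1 = list(m = m, protein = "P1", sequence = "AAA", offsets = "1")))
  f <- filter_fragments(t, min_fragments = 1, min_detected_per_condition = 1)
  d <- f$data
  expect_true(is.na(d$intensity[d$fragment_id == "p1_f1" & d$sample == "CTRL_R1"]))
  expect_true(is.na(d$intensity[d$fragment_id == "p1_f1" & d$sample == "CTRL_R3"]))
  expect_equal(d$intensity[d$fragment_id == "p1_f1" & d$sample == "CTRL_R2"], 2001)
})

test_that("empty tables pass through and total removal warns", {
  t <- fragment_table(
    data.frame(peptide_id = character(), fragment_id = character(),
               sample = character(), condition = character(),
               replicate = integer(), intensity = numeric()),
    data.frame(peptide_id = character(), protein = character(),
               sequence = character(), offsets = character()))
  expect_equal(nrow(filter_fragments(t)$data), 0)
  m <- matrix(rep(100, 6), nrow = 1, dimnames = list(NULL, samples6))
  low <- toy_fragments(list(p1 = list(m = m, protein = "P1", sequence = "AAA", offsets = "1")))
  expect_warning(filter_fragments(low, min_fragments = 1), "removed")
})

test_that("a 12-fragment toy table loses exactly the planted bad fragments", {
  # 12 fragments of one peptide; coherent profile rises strongly in treatment
  base_profile <- c(11, 11.2, 11.4, 14.2, 14.4, 14.6)
  set.seed(1)
  m <- matrix(NA_real_, 12, 6, dimnames = list(NULL, samples6))
  for (fi in 1:12) m[fi, ] <- 2^(base_profile + rnorm(6, 0, 0.05) + (fi - 6) * 0.1)
  # fragments 1-2: low intensity (below the 2000 cut everywhere)
  m[1, ] <- 2^(base_profile - 1) * 0 + 1500
  m[2, ] <- 1000
  # fragment 3: anti-correlated profile (falls in treatment)
  m[3, ] <- 2^rev(base_profile)
  # fragment 4: detected only once per condition
  m[4, c(2, 3, 5, 6)] <- NA
  t <- toy_fragments(list(p1 = list(m = m, protein = "P1", sequence = "AAA", offsets = "1")))
  f <- filter_fragments(t)
  left <- sort(unique(f$data$fragment_id))
  expect_equal(left, sort(paste0("p1_f", 5:12)))
  expect_equal(length(left), 8)
})

test_that("the fragment filter is idempotent", {
  net <- gen_prior_network(5, 8, 0.3, seed = 21)
  out <- gen_perturbation_dataset(net, "KIN01", seed = 22, dropout_rate = 0.15)
  once <- filter_fragments(out$fragments)
  twice <- filter_fragments(once)
  expect_identical(once$data, twice$data)
})

test_that("imputation follows the 20%-of-minimum rule and keeps observed values", {
  m <- matrix(c(21000, NA, 25000, 30000, NA, 31000), nrow = 2, byrow = TRUE,
              dimnames = list(NULL, samples6[c(1, 2, 3)]))
  t <- fragment_table(
    data.frame(peptide_id = "p1", fragment_id = rep(c("f1", "f2"), each = 3),
               sample = rep(samples6[1:3], 2), condition = "CTRL",
               replicate = rep(1:3, 2), intensity = c(m[1, ], m[2, ])),
    data.frame(peptide_id = "p1", protein = "P1", sequence = "AAA", offsets = "1"))
  i <- impute_missing(t)
  expect_equal(i$data$intensity[i$data$fragment_id == "f1"], c(21000, 0.2 * 21000, 25000))
  expect_equal(i$data$intensity[i$data$fragment_id == "f2"], c(30000, 0.2 * 30000, 31000))
  # no missing values: unchanged
  expect_identical(impute_missing(i)$data, i$data)
  # entirely missing fragment is dropped with a warning
  t$data$intensity[t$data$fragment_id == "f2"] <- NA
  expect_warning(i2 <- impute_missing(t), "cannot impute")
  expect_false("f2" %in% i2$data$fragment_id)
})

test_that("peptides map to 1-based protein positions with protein residue letters", {
  t <- list(peptides = data.frame(peptide_id = c("p1", "p2", "p3"),
                                  protein = c("A1", "A1", "A1"),
                                  sequence = c("SPSLK", "TAYSP", "QQQQQ"),
                                  offsets = c("1", "2,5", "1")))
  class(t) <- "fragment_table"
  proteome <- c(A1 = "MKTAYSPSLK")
  expect_warning(s <- map_sites(t, proteome), "excluded")
  p1 <- s[s$peptide_id == "p1", ]
  expect_equal(p1$residue, "S"); expect_equal(p1$position, 6L)
  expect_equal(p1$multiplicity, 1L)
  p2 <- s[s$peptide_id == "p2", ]
  expect_equal(p2$position, c(4L, 7L))
  expect_equal(p2$residue, c("A", "P"))
  expect_equal(p2$multiplicity, c(2L, 2L))
  expect_equal(attr(s, "excluded"), "p3")
})

test_that("differential statistics: forced fold changes and degenerate variance", {
  mk <- function(trt_mult) {
    ctrl <- c(4000, 4000, 4000)
    m <- matrix(c(ctrl, ctrl * trt_mult), nrow = 1,
                dimnames = list(NULL, samples6))
    toy_fragments(list(p1 = list(m = m, protein = "P1", sequence = "SAA", offsets = "1")))
  }
  proteome <- c(P1 = "SAAK")
  s <- map_sites(mk(2), proteome)
  d2 <- differential(mk(2), s, "TRT")
  expect_equal(d2$log2fc, 1)               # exactly 2x control
  d1 <- differential(mk(1), s, "TRT")
  expect_equal(d1$log2fc, 0)
  expect_equal(d1$p, 1)                    # identical values in both groups
  expect_error(differential(
    toy_fragments(list(p1 = list(m = matrix(c(4000, 4000, 4000, 4000), nrow = 1,
                                            dimnames = list(NULL, samples6[c(1, 2, 3, 4)])),
                                 protein = "P1", sequence = "SAA", offsets = "1"))),
    s, "TRT"), "fewer than 2 replicates")
})

test_that("swapping treatment and control negates every log2 fold change", {
  net <- gen_prior_network(5, 8, 0.3, seed = 31)
  out <- gen_perturbation_dataset(net, "KIN01", seed = 32)
  imp <- impute_missing(filter_fragments(out$fragments))
  s <- map_sites(imp, out$proteome)
  fwd <- differential(imp, s, "TRT_KIN01", "CTRL")
  rev <- differential(imp, s, "CTRL", "TRT_KIN01")
  m <- match(fwd$peptide_id, rev$peptide_id)
  expect_equal(fwd$log2fc, -rev$log2fc[m])
  expect_equal(fwd$p, rev$p[m])
})

test_that("BH adjustment is monotone and bounded by one", {
  net <- gen_prior_network(5, 8, 0.3, seed = 41)
  out <- gen_perturbation_dataset(net, "KIN01", seed = 42)
  imp <- impute_missing(filter_fragments(out$fragments))
  s <- map_sites(imp, out$proteome)
  d <- collapse_duplicate_sites(differential(imp, s, "TRT_KIN01"))
  expect_true(all(d$fdr <= 1))
  expect_true(all(d$fdr >= d$p - 1e-12))
  o <- order(d$p)
  expect_true(all(diff(d$fdr[o]) >= -1e-12))
})

test_that("duplicate sites collapse to the higher control signal with id tie-break", {
  d <- data.frame(peptide_id = c("pepB", "pepA", "pepC"),
                  protein = "P1", residue = "S", position = 6L, multiplicity = 1L,
                  treatment = "TRT", log2fc = c(1, 2, 3), p = c(0.01, 0.02, 0.03),
                  fdr = NA_real_, mean_control = c(100, 200, 200))
  class(d) <- c("diff_table", "data.frame")
  out <- collapse_duplicate_sites(d)
  expect_equal(nrow(out), 1)
  expect_equal(out$peptide_id, "pepA")  # 200 beats 100; pepA beats pepC on the tie
  # single peptide untouched
  single <- collapse_duplicate_sites(d[1, ])
  expect_equal(single$peptide_id, "pepB")
})
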