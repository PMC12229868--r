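make_npx_fixture <- function(n = 3) {
  tibble::tibble(
    sample_id = sprintf("s%d", seq_len(n)),
    person_id = sprintf("s%d", seq_len(n)),
    assay_id = "P001", panel = "A", dilution = 1,
    npx = seq_len(n) + 4, lod = 0, uloq = 12, qc_pass = TRUE
  )
}

test_that("reading a well-formed file round-trips", {
  path <- tempfile(fileext = ".csv")
  readr::write_csv(make_npx_fixture(), path)
  tbl <- read_npx_long(path)
  expect_equal(nrow(tbl), 3)
  expect_setequal(names(tbl), c("sample_id", "person_id", "assay_id", "panel",
                                "dilution", "npx", "lod", "uloq", "qc_pass"))
})

test_that("validation errors name the problem", {
  fx <- make_npx_fixture()
  path <- tempfile(fileext = ".csv")
  readr::write_csv(fx[, setdiff(names(fx), "uloq")], path)
  expect_error(read_npx_long(path), "uloq")

  dup <- dplyr::bind_rows(fx, fx[1, ])
  expect_error(validate_npx_long(dup), "duplicate.*s1", ignore.case = TRUE)

  bad <- fx
  bad$lod[2] <- 99
  expect_error(validate_npx_long(bad), "lod >= uloq")
})

dilution_fixture <- function() {
  # lod 0, uloq 10, mid 5: dilution 1 hugs the ULOQ, dilution 10 is centered
  samples <- sprintf("s%d", 1:6)
  tibble::tibble(
    sample_id = rep(samples, 2),
    person_id = rep(samples, 2),
    assay_id = "P001", panel = "A",
    dilution = rep(c(1, 10), each = 6),
    npx = c(9.2, 9.5, 9.4, 9.6, 9.3, 9.1, 5.2, 4.9, 5.1, 5.0, 4.8, 5.3),
    lod = 0, uloq = 10, qc_pass = TRUE
  )
}

test_that("dilution closest to the dynamic-range midpoint is selected", {
  expect_equal(select_dilution(dilution_fixture(), "P001"), 10)

  single <- dilution_fixture() |> dplyr::filter(dilution == 1)
  expect_equal(select_dilution(single, "P001"), 1)

  # exact tie in median distance: both dilutions 1 unit from the midpoint
  tie <- dilution_fixture()
  tie$npx <- rep(c(6, 4), each = 6)
  expect_equal(select_dilution(tie, "P001"), 1)
})

test_that("dilution selection is invariant to sample ordering", {
  fx <- dilution_fixture()
  shuffled <- fx[sample(nrow(fx)), ]
  expect_equal(select_dilution(fx), select_dilution(shuffled))
})

test_that("assays with no in-range values are flagged, not dropped", {
  fx <- dilution_fixture()
  fx$npx <- fx$npx + 20 # everything above ULOQ
  chosen <- select_dilution(fx)
  expect_equal(nrow(chosen), 1)
  expect_true(chosen$no_in_range)
})

test_that("linearity score matches hand computations", {
  fx <- dilution_fixture()
  # perfect behaviour: dilution 10 exactly log2(10) below dilution 1
  fx$npx[fx$dilution == 10] <- fx$npx[fx$dilution == 1] - log2(10)
  expect_equal(dilution_linearity_score(fx, "P001"), 0)

  # uniform offset of 0.25 log2 units
  off <- fx
  off$npx[off$dilution == 10] <- off$npx[off$dilution == 10] - 0.25
  expect_equal(dilution_linearity_score(off, "P001"), 0.25)

  single <- fx[fx$dilution == 1, ]
  expect_true(is.na(dilution_linearity_score(single, "P001")))
})

lod_fixture <- function(n_below_control, n_below_case) {
  persons <- c(sprintf("c%d", 1:6), sprintf("o%d", 1:6))
  group <- rep(c("control", "OA"), each = 6)
  npx <- rep(5, 12)
  npx[seq_len(n_below_control)] <- -1
  if (n_below_case > 0) npx[6 + seq_len(n_below_case)] <- -1
  list(
    tbl = tibble::tibble(sample_id = persons, person_id = persons,
                         assay_id = "P001", panel = "A", dilution = 1,
                         npx = npx, lod = 0, uloq = 10, qc_pass = TRUE),
    samples = tibble::tibble(person_id = persons, group = group,
                             age = 50, sex = "F", bmi = 25)
  )
}

test_that("below-LOD exclusion applies the more-than-max rule per group", {
  fx <- lod_fixture(3, 0)
  res <- filter_lod(fx$tbl, fx$samples, max_below = 2)
  expect_equal(res$excluded$assay_id, "P001")
  expect_equal(res$excluded$reason, "below_lod")
  expect_equal(nrow(res$data), 0)

  fx2 <- lod_fixture(2, 2)
  res2 <- filter_lod(fx2$tbl, fx2$samples, max_below = 2)
  expect_equal(nrow(res2$excluded), 0)
  expect_equal(sum(is.na(res2$data$npx)), 4) # cells masked, assay kept

  fx0 <- lod_fixture(0, 0)
  res0 <- filter_lod(fx0$tbl, fx0$samples, max_below = 2)
  expect_equal(nrow(res0$excluded), 0)
  expect_equal(sum(is.na(res0$data$npx)), 0)
})

test_that("lowering max_below never retains a previously excluded assay", {
  set.seed(41)
  for (i in 1:20) {
    n_b_c <- sample(0:5, 1); n_b_o <- sample(0:5, 1)
    fx <- lod_fixture(n_b_c, n_b_o)
    for (mb in 4:0) {
      hi <- filter_lod(fx$tbl, fx$samples, max_below = mb + 1)$excluded$assay_id
      lo <- filter_lod(fx$tbl, fx$samples, max_below = mb)$excluded$assay_id
      expect_true(all(hi %in% lo))
    }
  }
})

test_that("standardize centers, scales, and is idempotent", {
  m <- cbind(a = c(1, 2, 3), b = c(2, 4, 9))
  z <- standardize(m)
  expect_equal(unname(z[, "a"]), c(-1, 0, 1))
  expect_equal(colMeans(z), c(a = 0, b = 0))
  expect_equal(apply(z, 2, sd), c(a = 1, b = 1))
  expect_equal(standardize(z), z, tolerance = 1e-12)

  # missing cell: moments over non-missing values only
  m4 <- cbind(a = c(1, 2, 3, NA), b = c(5, 1, 2, 4))
  z4 <- standardize(m4)
  expect_equal(unname(z4[1:3, "a"]), (c(1, 2, 3) - 2) / 1)
  expect_true(is.na(z4[4, "a"]))

  expect_error(standardize(cbind(a = c(1, 1, 1), b = 1:3)), "a")
})

test_that("QC report partitions the assay set and flags planted failures", {
  cfg <- simulation_config(n_control = 8, n_case = 8,
                           panels = c(A = 10, B = 6),
                           dilution_factors = list(A = c(1, 20), B = 1),
                           network_proteins = character(0),
                           bad_assay_ids = "P003", low_assay_ids = "P012",
                           seed = 21)
  sim <- simulate_npx_dataset(cfg)
  qc <- qc_npx(sim$npx, sim$samples)
  rep <- qc$report
  expect_setequal(c(rep$retained, rep$excluded$assay_id),
                  unique(sim$npx$assay_id))
  expect_equal(rep$n_assays_in,
               length(rep$retained) + nrow(rep$excluded))
  expect_true("P003" %in% rep$excluded$assay_id[rep$excluded$reason == "nonlinearity"])
  expect_true("P012" %in% rep$excluded$assay_id[rep$excluded$reason == "below_lod"])
  # analysis table has one row per retained assay and sample
  expect_equal(nrow(qc$data), length(rep$retained) * 16)
})
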