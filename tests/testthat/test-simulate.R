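test_that("error model strings parse and bad ones fail", {
  m <- error_model("linker1:substitution:0.05", "bc2:deletion:0.01",
                   "linker2:substitution:0.02:2", "umi:insertion:0.1:1:3")
  expect_equal(nrow(m), 4L)
  expect_equal(m$count, c(1L, 1L, 2L, 1L))
  expect_equal(m$position, c("random", "random", "random", "3"))
  expect_equal(nrow(error_model()), 0L)
  expect_error(error_model("linker9:substitution:0.1"), "target")
  expect_error(error_model("linker1:flip:0.1"), "kind")
  expect_error(error_model("linker1:substitution:1.5"), "probability")
  expect_error(error_model("linker1:substitution"), "malformed")
})

test_that("a clean dataset has the promised shape and all-valid truth", {
  wl <- wl96()
  sim <- simulate_reads(3, 10, wl, seed = 1)
  expect_equal(nrow(sim$reads), 30L)
  expect_equal(nrow(sim$truth), 30L)
  expect_equal(length(unique(sim$truth$cell_barcode)), 3L)
  expect_true(all(sim$truth$expected_status == "valid"))
  expect_true(all(sim$truth$errors == ""))
  expect_true(all(nchar(sim$truth$cell_barcode) == 18L))
  expect_true(all(nchar(sim$truth$umi) == 8L))
  expect_true(all(sim$truth$pb_len >= 1 & sim$truth$pb_len <= 5))
  # every barcode block is a whitelist triple
  blocks <- c(substr(sim$truth$cell_barcode, 1, 6),
              substr(sim$truth$cell_barcode, 7, 12),
              substr(sim$truth$cell_barcode, 13, 18))
  expect_true(all(blocks %in% wl$entries))
})

test_that("identical seeds give identical datasets, including files", {
  wl <- wl96()
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  s1 <- simulate_reads(4, 8, wl, seed = 99, out_dir = d1)
  s2 <- simulate_reads(4, 8, wl, seed = 99, out_dir = d2)
  expect_identical(s1$reads, s2$reads)
  expect_identical(s1$truth, s2$truth)
  expect_identical(unname(tools::md5sum(s1$files[["r1"]])),
                   unname(tools::md5sum(s2$files[["r1"]])))
  expect_identical(unname(tools::md5sum(s1$files[["r2"]])),
                   unname(tools::md5sum(s2$files[["r2"]])))
  s3 <- simulate_reads(4, 8, wl, seed = 100)
  expect_false(identical(s1$reads$r1_seq, s3$reads$r1_seq))
})

test_that("single in-budget errors keep the truth valid, double ones flip it", {
  wl <- wl96()
  one_sub <- simulate_reads(5, 20, wl, seed = 7,
                            model = error_model("linker1:substitution:1"))
  expect_true(all(one_sub$truth$expected_status == "valid"))
  expect_true(all(one_sub$truth$errors == "linker1:substitution:1"))

  # two substitutions defeat the linker almost always; the rare exception is
  # a double edge substitution that still reads as one indel interpretation
  two_sub <- simulate_reads(5, 20, wl, seed = 7,
                            model = error_model("linker1:substitution:1:2"))
  expect_gt(mean(two_sub$truth$expected_status == "L1"), 0.95)

  # one deletion in each linker: each within its own budget
  both_del <- simulate_reads(5, 20, wl, seed = 8,
                             model = error_model("linker1:deletion:1",
                                                 "linker2:deletion:1"))
  expect_gt(mean(both_del$truth$expected_status == "valid"), 0.9)
})

test_that("infeasible cell counts are rejected", {
  wl <- barcode_whitelist(c("ACGTAC", "TGCATG"))
  expect_error(simulate_reads(9, 5, wl, seed = 1), "triples")
  sim <- simulate_reads(8, 2, wl, seed = 1)
  expect_equal(length(unique(sim$truth$cell_barcode)), 8L)
})

test_that("extraction reproduces the oracle's expected status on every read", {
  wl <- wl96()
  cfg <- read_structure()
  classes <- list(
    error_model(),
    error_model("linker1:substitution:0.5"),
    error_model("linker1:deletion:0.5"),
    error_model("linker1:insertion:0.5"),
    error_model("linker2:deletion:0.5"),
    error_model("linker2:insertion:0.5"),
    error_model("bc1:substitution:0.5"),
    error_model("bc2:deletion:0.5"),
    error_model("bc3:substitution:0.5"),
    error_model("umi:deletion:0.5"),
    error_model("phase:deletion:0.5"),
    error_model("flanker_pre:substitution:0.5:2"),
    error_model("linker1:substitution:0.3:2", "linker2:substitution:0.3:2")
  )
  seedi <- 500L
  for (m in classes) {
    sim <- simulate_reads(15, 10, wl, seed = seedi, model = m, cfg = cfg)
    seedi <- seedi + 1L
    tags <- extract_tags(sim$reads, cfg, wl)
    same_status <- ifelse(sim$truth$expected_status == "valid",
                          tags$status == "valid",
                          tags$status == "invalid" &
                            tags$error_code == sim$truth$expected_status)
    expect_true(all(same_status),
                info = paste("model:", paste(m$target, m$kind, collapse = ";")))
    v <- sim$truth$expected_status == "valid"
    expect_equal(tags$cell_barcode[v], sim$truth$expected_barcode[v])
    expect_equal(tags$umi[v], sim$truth$expected_umi[v])
  }
})

test_that("observed error fractions track the model probabilities", {
  wl <- wl96()
  sim <- simulate_reads(40, 100, wl, seed = 64,
                        model = error_model("linker1:substitution:0.1:2"))
  tags <- extract_tags(sim$reads, read_structure(), wl)
  d <- error_distribution(tags)
  p <- 0.1
  se <- sqrt(p * (1 - p) / nrow(tags))
  expect_lt(abs(d$fraction[d$code == "L1"] - p), 3 * se)
})
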