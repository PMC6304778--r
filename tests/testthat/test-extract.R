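test_that("structure validation enforces gap, offset and length in order", {
  cfg <- toy_cfg()
  h <- function(start, width = 15L) list(start = start, width = width)
  # canonical 21-nt gap, 8 preceding bases
  expect_equal(validate_structure(h(9), h(30), 70, cfg), "ok")
  # too few bases before linker 1 (phase block + BC1 need 7)
  expect_equal(validate_structure(h(6), h(27), 70, cfg), "P")
  # boundary: exactly min_l1_start preceding bases is acceptable
  expect_equal(validate_structure(h(8), h(29), 70, cfg), "ok")
  # gap outside {20, 21, 22}
  expect_equal(validate_structure(h(9), h(34), 70, cfg), "D")
  # gap 20/22 absorb a single indel
  expect_equal(validate_structure(h(9), h(29), 70, cfg), "ok")
  expect_equal(validate_structure(h(9), h(31), 70, cfg), "ok")
  # but not in strict mode
  strict <- toy_cfg(strict_gap = TRUE)
  expect_equal(validate_structure(h(9), h(29), 70, strict), "D")
  # gap fine but BC2 block implies two indels (L1 deletion + gap 22)
  expect_equal(validate_structure(h(9, 14L), h(31), 70, cfg), "D")
  # read too short for BC3 + flankers + UMI after linker 2
  expect_equal(validate_structure(h(9), h(30), 40, cfg), "S")
  # minimal sufficient length: end2 + 6 + 3 + 8 + 3
  expect_equal(validate_structure(h(9), h(30), 64, cfg), "ok")
  expect_equal(validate_structure(h(9), h(30), 63, cfg), "S")
  # D is checked before P
  expect_equal(validate_structure(h(5), h(30), 60, cfg), "D")
})

test_that("flanker check counts mismatches across both trinucleotides", {
  cfg <- toy_cfg()
  mk <- function(pre, post) paste0("ACGTAC", pre, "AACCGGTT", post)
  expect_equal(check_flankers(mk("ACG", "GAC"), 6, cfg), "ok")
  expect_equal(check_flankers(mk("ACT", "GAC"), 6, cfg), "ok")   # 1 mismatch
  expect_equal(check_flankers(mk("ACG", "GAT"), 6, cfg), "ok")   # 1 mismatch
  expect_equal(check_flankers(mk("ACT", "GAT"), 6, cfg), "T")    # 2 total
  expect_equal(check_flankers(mk("TTT", "GAC"), 6, cfg), "T")
  # N is a mismatch
  expect_equal(check_flankers(mk("ACN", "GAN"), 6, cfg), "T")
})

test_that("clean reads give the concatenated corrected barcode and verbatim UMI", {
  cfg <- toy_cfg()
  wl <- toy_wl()
  t <- extract_tags(toy_read(), cfg, wl)
  expect_tag(t, "valid", toy_barcode, "AACCGGTT")
  expect_true(is.na(t$error_code))
})

test_that("single linker edits leave the result identical to the clean read", {
  cfg <- toy_cfg()
  wl <- toy_wl()
  rd <- toy_read()
  # substitution inside L2
  expect_tag(extract_tags(sub_at(rd, 32, "T"), cfg, wl), "valid",
             toy_barcode, "AACCGGTT")
  # deletion inside L1 shifts all downstream coordinates by -1
  expect_tag(extract_tags(del_at(rd, 16), cfg, wl), "valid",
             toy_barcode, "AACCGGTT")
  # insertion inside L1
  expect_tag(extract_tags(ins_at(rd, 16, "C"), cfg, wl), "valid",
             toy_barcode, "AACCGGTT")
})

test_that("reads exceeding the linker budget carry that linker's code", {
  cfg <- toy_cfg()
  wl <- toy_wl()
  rd <- toy_read()
  two_subs_l1 <- sub_at(sub_at(rd, 11, "C"), 17, "A")
  expect_tag(extract_tags(two_subs_l1, cfg, wl), "invalid", code = "L1")
  two_subs_l2 <- sub_at(sub_at(rd, 32, "T"), 38, "C")
  expect_tag(extract_tags(two_subs_l2, cfg, wl), "invalid", code = "L2")
  both <- sub_at(sub_at(two_subs_l1, 32, "T"), 38, "C")
  expect_tag(extract_tags(both, cfg, wl), "invalid", code = "LX")
  expect_tag(extract_tags(strrep("A", 20), cfg, wl), "invalid", code = "LX")
})

test_that("structural failures get D/P/S/T codes", {
  cfg <- toy_cfg()
  wl <- toy_wl()
  # two extra bases in BC2: gap 23
  bad_gap <- toy_read(bc2 = "TGGGCATG")
  expect_tag(extract_tags(bad_gap, cfg, wl), "invalid", code = "D")
  # phase block absent: linker 1 starts after only 6 bases
  short_pb <- toy_read(pb = "")
  expect_tag(extract_tags(short_pb, cfg, wl), "invalid", code = "P")
  # read truncated inside the UMI
  trunc <- substr(toy_read(tail = ""), 1, nchar(toy_read(tail = "")) - 5)
  expect_tag(extract_tags(trunc, cfg, wl), "invalid", code = "S")
  # both flankers mutated
  r <- toy_read()
  bad_fl <- sub_at(sub_at(r, 30 + 15 + 6 + 1, "T"), 30 + 15 + 6 + 3 + 8 + 2, "T")
  expect_tag(extract_tags(bad_fl, cfg, wl), "invalid", code = "T")
})

test_that("unmatchable barcode blocks give B and never a guess", {
  cfg <- toy_cfg()
  wl <- toy_wl()
  # BC1 two substitutions away from every entry
  t <- extract_tags(toy_read(bc1 = "AGGTAT"), cfg, wl)
  expect_tag(t, "invalid", code = "B")
  # ambiguity between entries is a failure, not an arbitrary pick
  wl2 <- barcode_whitelist(c("AAAAAA", "AAAAAT", "TGCATG", "GATCGA", "ACGTAC"))
  t2 <- extract_tags(toy_read(bc1 = "AAAAAG"), cfg, wl2)
  expect_tag(t2, "invalid", code = "B")
})

test_that("structural failures take precedence over content failures", {
  cfg <- toy_cfg()
  wl <- toy_wl()
  rd <- toy_read(bc1 = "AGGTAT")  # bad barcode ...
  rd <- sub_at(sub_at(rd, 11, "C"), 17, "A")  # ... and a dead linker 1
  expect_tag(extract_tags(rd, cfg, wl), "invalid", code = "L1")
})

test_that("phase-block sweep recovers every error-free read exactly", {
  cfg <- toy_cfg()
  wl <- toy_wl()
  pbs <- vapply(1:10, function(k) paste(rep("G", k), collapse = ""), "")
  reads <- vapply(pbs, function(pb) toy_read(pb = pb), "")
  t <- extract_tags(unname(reads), cfg, wl)
  expect_true(all(t$status == "valid"))
  expect_true(all(t$cell_barcode == toy_barcode))
  expect_true(all(t$umi == "AACCGGTT"))
})

test_that("the reported UMI is always a verbatim substring of Read 1", {
  wl <- wl96()
  cfg <- read_structure()
  sim <- simulate_reads(20, 25, wl, seed = 301,
                        model = error_model("linker1:deletion:0.3",
                                            "linker2:insertion:0.3",
                                            "umi:substitution:0.3"))
  t <- extract_tags(sim$reads, cfg, wl)
  v <- t$status == "valid"
  expect_gt(sum(v), 0)
  expect_true(all(mapply(grepl, t$umi[v], sim$reads$r1_seq[v], fixed = TRUE)))
})

test_that("a data frame in gives the same tibble back with tag columns added", {
  cfg <- toy_cfg()
  wl <- toy_wl()
  df <- tibble::tibble(read_id = c("a", "b"), r1_seq = c(toy_read(), strrep("A", 20)),
                       extra = c(1, 2))
  t <- extract_tags(df, cfg, wl)
  expect_equal(t$read_id, c("a", "b"))
  expect_equal(t$extra, c(1, 2))
  expect_equal(t$status, c("valid", "invalid"))
})
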