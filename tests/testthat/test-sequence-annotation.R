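test_that("FASTA parsing builds validated records and round-trips", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">q1 some description", "MNPAV"), f)
  recs <- read_fasta(f)
  expect_length(recs, 1L)
  expect_equal(recs$q1$peptide, "MNPAV")
  expect_equal(recs$q1$description, "some description")

  writeLines(c(">a", "MAG", ">a", "MAV"), f)
  expect_error(read_fasta(f), "duplicate.*a")

  # 3-entry cohort written by the generator, re-read: identical sequences
  cohort <- generate_aquaporin_cohort(
    cohort_recipe(n = c(Eglp = 1, Prip = 1, Glp = 1), divergence = 0.1,
                  seed = 7), panel = PANEL, fasta = f)
  back <- read_fasta(f)
  expect_identical(names(back), names(cohort$records))
  for (id in names(back))
    expect_identical(back[[id]]$peptide, cohort$records[[id]]$peptide)
})

test_that("record validation names the offending residue and enforces non-emptiness", {
  expect_error(aqp_record("r1", "MAB2"), "invalid residue 'B' at position 3")
  expect_error(aqp_record("r1", ""), "empty")
  expect_equal(aqp_record("r1", "mkt*")$peptide, "MKT")  # stop stripped
  expect_silent(aqp_record("r1", "MKTX"))                # ambiguous X allowed
})

test_that("NPA scan finds planted boxes, labels halves, and matches a brute-force oracle", {
  bg <- strrep("G", 260)
  pep <- bg
  substr(pep, 60, 62) <- "NPA"
  substr(pep, 180, 182) <- "NPA"
  hits <- scan_npa(aqp_record("planted", pep))
  expect_equal(hits$start, c(60L, 180L))
  expect_equal(hits$half, c("N", "C"))

  expect_equal(nrow(scan_npa(aqp_record("polyA", strrep("A", 200)))), 0L)

  # packaged template and every panel reference agree with the oracle
  for (rec in c(list(AQP4_REC), PANEL$records)) {
    expect_equal(scan_npa(rec)$start, oracle_npa_scan(rec$peptide),
                 info = rec$id)
  }

  # strict mode restricts the third slot
  strict <- scan_npa(aqp_record("s", "GGNPSGG"), alike = "A")
  expect_equal(nrow(strict), 0L)
})

test_that("template alignment maps residues one-to-one and respects offsets", {
  self <- align_to_template(AQP4_REC, TMPL)
  expect_equal(self$pairs$template_index, self$pairs$query_index)
  expect_equal(self$fraction_template_covered, 1)

  ext <- aqp_record("ext", paste0(strrep("G", 10), TMPL$template_peptide))
  m <- align_to_template(ext, TMPL)
  core <- m$pairs[m$pairs$template_index >= TMPL$trim_range[1] &
                    m$pairs$template_index <= TMPL$trim_range[2], ]
  expect_true(all(core$query_index == core$template_index + 10L))

  # scattered substitutions outside annotated sites leave the mapping intact
  pep <- TMPL$template_peptide
  for (pos in c(10L, 50L, 130L, 170L, 240L))
    substr(pep, pos, pos) <- if (substr(pep, pos, pos) == "W") "Y" else "W"
  m2 <- align_to_template(aqp_record("sub", pep), TMPL)
  ann <- unlist(TMPL$arR_positions)
  for (p in ann)
    expect_equal(m2$pairs$query_index[m2$pairs$template_index == p], p)
})

test_that("low-coverage alignments abort with a coverage-carrying condition", {
  frag <- aqp_record("frag", substr(TMPL$template_peptide, 1, 60))
  err <- expect_error(align_to_template(frag, TMPL),
                      class = "eglporin_low_coverage")
  expect_lt(err$coverage, 0.5)
})

test_that("ar/R extraction reports the literature anchor residues", {
  f4 <- annotate_record(AQP4_REC, TMPL)$filter
  expect_equal(f4$tmd5_index, 201L)
  expect_equal(f4$tmd5_aa, "H")
  expect_true(f4$tmd5_charged)

  fpv <- annotate_record(PANEL$records$PvAqp2_syn, TMPL)$filter
  expect_equal(fpv$tmd5_index, 174L)
  expect_equal(fpv$tmd5_aa, "A")
  expect_false(fpv$tmd5_charged)

  fbg <- annotate_record(PANEL$records$BgAqp_syn, TMPL)$filter
  expect_equal(fbg$tmd5_index, 197L)
  expect_equal(fbg$tmd5_aa, "H")
})

test_that("extraction is invariant to terminal tails up to 100 residues", {
  set.seed(11)
  for (i in 1:10) {
    nt <- paste(sample(c("G", "S", "A", "P"), sample(0:100, 1), TRUE),
                collapse = "")
    ct <- paste(sample(c("G", "S", "A", "P"), sample(0:100, 1), TRUE),
                collapse = "")
    rec <- aqp_record("tail", paste0(nt, PANEL$records$PvAqp2_syn$peptide, ct))
    f <- annotate_record(rec, TMPL)$filter
    expect_equal(f$tmd5_aa, "A")
    expect_equal(f$tmd5_index, 174L + nchar(nt))
  }
})

test_that("planted ar/R quartets are recovered under background divergence", {
  # seeded replicates at 20% per-site divergence; planted quartet recovered
  meta <- jsonlite::read_json(
    system.file("extdata", "reference_panel_synthetic.json",
                package = "eglporin"), simplifyVector = TRUE)
  n_rep <- 500L
  sizes <- c(Eglp = 167L, Prip = 167L, Drip = 166L)
  cohort <- generate_aquaporin_cohort(
    cohort_recipe(n = sizes, divergence = 0.2, seed = 202), panel = PANEL)
  planted_pos <- lapply(meta, function(m) unlist(m$arR_positions))
  ref_of <- setNames(names(PANEL$records), PANEL$subfamilies)
  ok <- 0L
  for (id in names(cohort$records)) {
    truth <- cohort$truth[cohort$truth$id == id, ]
    f <- tryCatch(annotate_record(cohort$records[[id]], TMPL)$filter,
                  error = function(e) NULL)
    if (is.null(f)) next
    want <- planted_pos[[ref_of[[truth$subfamily]]]]
    got <- setNames(f$residues$query_index, f$residues$label)
    if (all(got[names(want)] == want) && f$tmd5_aa == truth$tmd5_aa)
      ok <- ok + 1L
  }
  expect_gte(ok / n_rep, 0.99)
})

test_that("annotation is deterministic and the cohort table carries all columns", {
  recs <- list(AQP4_REC, PANEL$records$PvAqp2_syn, PANEL$records$BgAqp_syn)
  a1 <- annotate_cohort(recs, TMPL)
  a2 <- annotate_cohort(recs, TMPL)
  expect_identical(a1$table, a2$table)
  expect_named(a1$table, c("id", "npa1", "npa2", "tmd2_aromatic",
                           "tmd5_index", "tmd5_aa", "le1", "le2", "coverage"))
  expect_equal(nrow(a1$errors), 0L)
})
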