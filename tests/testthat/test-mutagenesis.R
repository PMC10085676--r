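test_that("substitutions edit in place without shifting coordinates", {
  wt <- ztp_wt_synthetic()
  mut <- apply_mutation(wt, mutation_spec("SUBSTITUTION", 108, "C"))
  expect_identical(construct_length(mut), construct_length(wt))
  expect_identical(substr(mut$sequence, 108, 108), "C")
  expect_identical(mut$regions, wt$regions)
  expect_error(apply_mutation(wt, mutation_spec("SUBSTITUTION", 108, "G")),
               "no-op")
  expect_error(apply_mutation(wt, mutation_spec("SUBSTITUTION", 1000, "G")),
               "beyond")
})

test_that("deletions shift all downstream regions by -1", {
  wt <- ztp_wt_synthetic()
  mut <- apply_mutation(wt, mutation_spec("DELETION", 26))
  expect_identical(construct_length(mut), construct_length(wt) - 1L)
  expect_identical(region_of(mut, "invader")$start,
                   region_of(wt, "invader")$start - 1L)
  expect_identical(region_of(mut, "polyU")$start,
                   region_of(wt, "polyU")$start - 1L)
  expect_identical(region_of(mut, "PK")$end, region_of(wt, "PK")$end - 1L)
  expect_identical(region_of(mut, "P1"), region_of(wt, "P1"))
})

test_that("insertions land immediately 3' of the stated position", {
  wt <- ztp_wt_synthetic()
  mut <- apply_mutation(wt, mutation_spec("INSERTION", 110, "A"))
  expect_identical(construct_length(mut), construct_length(wt) + 1L)
  expect_identical(substr(mut$sequence, 110, 112),
                   paste0(substr(wt$sequence, 110, 110), "A",
                          substr(wt$sequence, 111, 111)))
  # insertion inside the invader extends it; poly-U shifts
  expect_identical(region_of(mut, "invader")$end,
                   region_of(wt, "invader")$end + 1L)
  expect_identical(region_of(mut, "polyU")$start,
                   region_of(wt, "polyU")$start + 1L)
})

test_that("mutation names follow the reference-numbering grammar", {
  wt <- ztp_wt_synthetic()
  sub <- mutation_spec("SUBSTITUTION", 108, "C")
  del <- mutation_spec("DELETION", 26)
  ins <- mutation_spec("INSERTION", 108, "AAA")
  expect_identical(name_mutation(sub, wt), "G108C")
  expect_identical(name_mutation(del, wt), "A26Δ")
  expect_identical(name_mutation(ins, wt), "108insAAA")

  for (nm in c("G108C", "A26Δ", "108insAAA")) {
    expect_identical(name_mutation(parse_mutation_name(nm, wt), wt), nm)
  }
  # aliases parse to the same spec
  expect_identical(parse_mutation_name("A26del", wt),
                   parse_mutation_name("A26Δ", wt))
  expect_identical(parse_mutation_name("G108-U109insAAA", wt),
                   parse_mutation_name("108insAAA", wt))
  expect_error(parse_mutation_name("A100G", wt), "reference has")
  expect_error(parse_mutation_name("G108-C110insA", wt), "adjacent")
  expect_error(parse_mutation_name("garbage", wt), "cannot parse")
})

test_that("mismatch scan complements each paired invader base", {
  wt <- ztp_wt_synthetic()
  lib <- scan_mismatch(wt)
  expect_true("G108C" %in% lib$mutants$name)
  aln <- align_construct(wt)
  expect_identical(nrow(lib$mutants),
                   sum(aln$columns$kind %in% c("WC", "WOBBLE")))
  # every mutant's duplex gains a mismatch element (next to a natural bulge
  # the optimal alignment may slide the pairings by one, moving its r)
  for (i in seq(1, nrow(lib$mutants), by = 3)) {
    mut <- lib$mutants$construct[[i]]
    els <- annotate_elements(align_construct(mut), mut)
    expect_true(any(els$kind == "MISMATCH"))
  }
  # on the bulge-free corrected scaffold the mismatch lands exactly at r
  perfect <- perfect_invader(wt)$construct
  plib <- scan_mismatch(perfect)
  for (i in seq_len(nrow(plib$mutants))) {
    mut <- plib$mutants$construct[[i]]
    els <- annotate_elements(align_construct(mut), mut)
    expect_true(plib$mutants$r[i] %in% els$r[els$kind == "MISMATCH"])
  }
})

test_that("deletion and wobble scans include the named reference mutants", {
  wt <- ztp_wt_synthetic()
  expect_true("G108Δ" %in% scan_deletion(wt)$mutants$name)
  perfect <- perfect_invader(wt)$construct
  wob <- scan_wobble(perfect)
  expect_true("C110U" %in% wob$mutants$name)
  reversed <- wob$mutants[wob$mutants$note != "", ]
  expect_true(all(grepl("^A\\d+G$", reversed$name)))
  expect_false(any(grepl("^A\\d+G$",
                         wob$mutants$name[wob$mutants$note == ""])))
  # excluding reversed-direction wobbles leaves only C->U mutants
  strict <- scan_wobble(perfect, include_reversed = FALSE)
  expect_true(all(grepl("^C\\d+U$", strict$mutants$name)))
})

test_that("bulge scan indexes insertions from the nucleation site", {
  wt <- ztp_wt_synthetic()
  perfect <- perfect_invader(wt)$construct
  lib <- scan_bulge(perfect, 1)
  at3 <- lib$mutants[lib$mutants$r == 3L, ]
  expect_identical(nrow(at3), 1L)
  expect_identical(at3$spec[[1]]$position, 110L)  # between C110 and C111
  mutant_seq <- at3$construct[[1]]$sequence
  expect_identical(substr(mutant_seq, 110, 112), "CAC")
  expect_error(scan_bulge(perfect, 4), "1, 2 or 3")
  lib3 <- scan_bulge(perfect, 3)
  expect_true(all(vapply(lib3$mutants$spec, function(s) s$alt, "") == "AAA"))
})

test_that("perfect invader correction removes all noncomplementary elements", {
  wt <- ztp_wt_synthetic()
  pf <- perfect_invader(wt)
  kinds <- vapply(pf$specs, function(s) s$kind, "")
  expect_identical(length(pf$specs), 5L)
  expect_identical(sum(kinds == "SUBSTITUTION"), 3L)
  expect_identical(sum(kinds == "DELETION"), 2L)
  names <- vapply(pf$specs, name_mutation, "", reference = wt)
  expect_true(all(c("U111C", "G112A", "U115Δ", "C118Δ") %in% names))
  els <- annotate_elements(align_construct(pf$construct), pf$construct)
  expect_identical(nrow(els), 0L)
  # idempotent: correcting the corrected construct changes nothing
  pf2 <- perfect_invader(pf$construct)
  expect_identical(pf2$construct$sequence, pf$construct$sequence)
  expect_identical(length(pf2$specs), 0L)
})

test_that("libraries are duplicate-free and diff back to their specs", {
  wt <- ztp_wt_synthetic()
  libs <- list(scan_mismatch(wt), scan_deletion(wt),
               scan_bulge(wt, 1), scan_bulge(wt, 2), scan_wobble(wt))
  for (lib in libs) {
    seqs <- vapply(lib$mutants$construct, function(x) x$sequence, "")
    expect_identical(anyDuplicated(seqs), 0L)
    for (i in seq_len(nrow(lib$mutants))) {
      inferred <- riboswitchEP:::infer_mutation(wt$sequence, seqs[i])
      expect_identical(unclass(inferred), unclass(lib$mutants$spec[[i]]))
    }
  }
})

test_that("mutants preserve construct region invariants", {
  wt <- ztp_wt_synthetic()
  for (lib in list(scan_deletion(wt), scan_bulge(wt, 3))) {
    for (mut in lib$mutants$construct) {
      expect_s3_class(mut, "construct")  # construct() validated on build
      inv <- region_of(mut, "invader")
      pu <- region_of(mut, "polyU")
      expect_lt(inv$end, pu$start)
    }
  }
})
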