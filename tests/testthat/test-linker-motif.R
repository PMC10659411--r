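test_that("boundary projection through an identity alignment is the identity", {
  seqs <- rep("MKVLQAWPFYHE", 3)
  msa <- new_msa(c("ref", "s1", "s2"), seqs)
  ref <- reference_boundaries("ref", beta11_end = 4, alpha5_start = 9)
  ann <- project_boundaries(msa, ref)
  expect_equal(ann$start, rep(5L, 3))
  expect_equal(ann$end, rep(8L, 3))

  expect_error(project_boundaries(msa, reference_boundaries("zz", 4, 9)),
               "'zz' not in alignment")
})

test_that("insertions and deletions shift projected linkers correctly", {
  # s1 has a 5-residue insertion inside the linker region of ref
  msa <- new_msa(c("ref", "s1"),
                 c("MKVLQA-----WPFYHE",
                   "MKVLQAGGGGGWPFYHE"), check_all_gap = FALSE)
  ref <- reference_boundaries("ref", beta11_end = 4, alpha5_start = 9)
  ann <- project_boundaries(msa, ref)
  expect_equal(ann$end[1] - ann$start[1] + 1, 4L)
  expect_equal(ann$end[2] - ann$start[2] + 1, 9L)  # 5 residues longer

  # a row with nothing between the boundary columns gets a null annotation
  msa <- new_msa(c("ref", "gappy"),
                 c("MKVLQAWPFYHE", "MKVL----FYHE"), check_all_gap = FALSE)
  ann <- project_boundaries(msa, ref)
  expect_true(is.na(ann$start[2]) && is.na(ann$end[2]))
})

test_that("tetrapeptide extraction reports every linker aspartate in order", {
  rec <- list(id = "x", sequence = "MKVLFASDGPWQHE")
  #                        linker:     5..10 (FASDGP)
  sites <- find_tetrapeptide_sites(rec, list(start = 5L, end = 10L))
  expect_equal(nrow(sites), 1)
  expect_equal(sites$tetrapeptide, "FASD")
  expect_equal(sites$p1_position, 8L)
  expect_equal(sites$p1_prime, "G")
  expect_equal(sites$p2_prime, "P")

  # no aspartate -> empty
  rec2 <- list(id = "y", sequence = "MKAAAAWQ")
  expect_equal(nrow(find_tetrapeptide_sites(rec2, list(start = 3L, end = 6L))), 0)

  # multiple aspartates are all listed
  rec3 <- list(id = "z", sequence = "WWWDAADAAWWW")
  sites <- find_tetrapeptide_sites(rec3, list(start = 4L, end = 9L))
  expect_equal(sites$p1_position, c(4L, 7L))
  expect_equal(sites$tetrapeptide, c("WWWD", "DAAD"))

  # left padding with X near the protein start; X context past the end
  rec4 <- list(id = "w", sequence = "MDKAAD")
  sites <- find_tetrapeptide_sites(rec4, list(start = 1L, end = 6L))
  expect_equal(sites$tetrapeptide, c("XXMD", "KAAD"))
  expect_equal(sites$p1_prime, c("K", "X"))
  expect_equal(sites$p2_prime, c("A", "X"))
})

test_that("classification reproduces the validated motif calls", {
  expect_equal(classify_tetrapeptide("YVAD")$site_class, "caspase1_like")
  expect_equal(classify_tetrapeptide("FASD")$site_class, "caspase1_like")
  expect_equal(classify_tetrapeptide("FVSD")$site_class, "caspase1_like")
  expect_equal(classify_tetrapeptide("AAAD")$site_class, "other_asp")
  expect_equal(classify_tetrapeptide("DAVD")$site_class, "caspase3_like")
  expect_equal(classify_tetrapeptide("DEVD")$site_class, "caspase3_like")
  expect_error(classify_tetrapeptide("YVAA"), "malformed")
  expect_error(classify_tetrapeptide("AD"), "malformed")

  # context scoring: bulky P4 (2) + small P1' (2) + G bonus (1) + P P2' (1)
  expect_equal(classify_tetrapeptide("FASD", "G", "P")$score, 6L)
  expect_equal(classify_tetrapeptide("FASD", "A", "W")$score, 4L)
  expect_equal(classify_tetrapeptide("AAAD", "G", "P")$score, 4L)
})

test_that("classification is a total, disjoint partition of D-terminal space", {
  tps <- apply(expand.grid(AA20, AA20, AA20, stringsAsFactors = FALSE),
               1, paste, collapse = "")
  tps <- paste0(tps, "D")
  expect_equal(length(tps), 8000)
  sites <- tibble::tibble(sequence_id = "s", tetrapeptide = tps,
                          p1_position = 4L, p1_prime = "X", p2_prime = "X")
  out <- classify_sites(sites)
  expect_true(all(out$site_class %in%
                    c("caspase1_like", "caspase3_like", "other_asp")))
  counts <- table(out$site_class)
  # every DxxD is caspase-3-like: 20^2 P3/P2 choices with P4 = D
  expect_equal(unname(counts["caspase3_like"]), 400L)
  # bulky non-D P4: 7 residues x 400
  expect_equal(unname(counts["caspase1_like"]), 7L * 400L)
  expect_equal(sum(counts), 8000L)
  # determinism
  expect_identical(classify_sites(sites), out)
})

test_that("YVAD-likeness follows the substitution-table arithmetic", {
  expect_true(is_yvad_like("YVAD"))
  sub <- blosum62()
  score_vs_yvad <- function(tp) {
    ch <- strsplit(tp, "")[[1]]
    sum(sub[cbind(ch, c("Y", "V", "A", "D"))])
  }
  for (tp in c("FVSD", "YIAD", "FASD", "LVAD", "WWWD")) {
    expect_equal(is_yvad_like(tp), score_vs_yvad(tp) >= 15, info = tp)
  }
  # hand values: YIAD = 7+3+4+6 = 20 (like), FVSD = 3+4+1+6 = 14 (not)
  expect_equal(score_vs_yvad("YIAD"), 20)
  expect_true(is_yvad_like("YIAD"))
  expect_equal(score_vs_yvad("FVSD"), 14)
  expect_false(is_yvad_like("FVSD"))
})

test_that("N-terminal caspase-3 scanning finds DxxD only", {
  rec <- list(id = "n", sequence = "MKDEVDGPAAAWWWDAVDWW")
  hits <- scan_caspase3_nterm(rec, c(1L, 20L))
  expect_equal(hits$tetrapeptide, c("DEVD", "DAVD"))
  expect_equal(hits$p1_position, c(6L, 18L))
  expect_true(all(hits$site_class == "caspase3_like"))

  # range restriction: site must lie entirely inside
  hits <- scan_caspase3_nterm(rec, c(1L, 10L))
  expect_equal(hits$tetrapeptide, "DEVD")
  expect_equal(nrow(scan_caspase3_nterm(list(id = "q", sequence = "MKAAAA"),
                                        c(1L, 6L))), 0)
})

test_that("logo information content matches the closed forms", {
  sites <- tibble::tibble(tetrapeptide = rep("YVAD", 12))
  logo <- build_logo(sites, correction = FALSE)
  expect_equal(logo$information_content, rep(log2(20), 4), tolerance = 1e-9)
  expect_equal(rowSums(logo$frequency_matrix), rep(1, 4), ignore_attr = TRUE)

  # uniform position -> IC 0
  sites <- tibble::tibble(tetrapeptide = paste0(AA20, "VAD"))
  logo <- build_logo(sites, correction = FALSE)
  expect_equal(logo$information_content[1], 0, tolerance = 1e-9)

  # small-sample correction: n = 10 conserved-P1 sites
  sites <- tibble::tibble(tetrapeptide = rep("YVAD", 10))
  logo <- build_logo(sites, correction = TRUE)
  expect_equal(logo$information_content[4],
               log2(20) - 0 - 19 / (2 * log(2) * 10), tolerance = 1e-9)
  expect_error(build_logo(sites[0, ]), "no sites")
})

test_that("merging distinct site sets never increases information content", {
  set.seed(19)
  rand_sites <- function(n, pool) {
    tibble::tibble(tetrapeptide = paste0(
      sample(pool, n, TRUE), sample(pool, n, TRUE),
      sample(pool, n, TRUE), "D"))
  }
  for (i in 1:10) {
    s1 <- rand_sites(15, c("Y", "F", "V"))
    s2 <- rand_sites(15, AA20)
    ic1 <- build_logo(s1, correction = FALSE)$information_content
    ic12 <- build_logo(dplyr::bind_rows(s1, s2),
                       correction = FALSE)$information_content
    # mixing in a maximally diverse set cannot sharpen any position
    expect_true(all(ic12 <= ic1 + 1e-9))
  }
})

test_that("hydropathy profiles match the embedded scale", {
  expect_equal(hydropathy_profile(strrep("I", 9), 9), 4.5)
  expect_equal(hydropathy_profile(strrep("R", 9), 9), -4.5)
  kd <- kyte_doolittle_scale()
  expect_equal(hydropathy_profile("IRIRI", 5),
               mean(kd[c("I", "R", "I", "R", "I")]))
  expect_equal(length(hydropathy_profile(strrep("A", 20), 7)), 14)
  expect_error(hydropathy_profile("MKV", 4), "window")
})

test_that("clade summaries count one vote per record", {
  records <- tibble::tibble(id = c("b1", "b2", "b3", "r1"),
                            clade = c("bird", "bird", "bird", "reptile"))
  sites <- tibble::tibble(
    sequence_id = c("b1", "b1", "b2", "r1"),
    tetrapeptide = c("YVAD", "YIAD", "FVSD", "AAAD"),
    p1_position = c(10L, 20L, 11L, 9L),
    p1_prime = "G", p2_prime = "P")
  sites <- classify_sites(sites)
  sites$yvad_like <- is_yvad_like(sites$tetrapeptide) &
    sites$site_class == "caspase1_like"
  out <- clade_summary(sites, records)
  bird <- out[out$clade == "bird", ]
  expect_equal(bird$n_sequences, 3L)
  expect_equal(bird$n_with_caspase1_like, 2L)  # b1 (twice -> once), b2
  expect_equal(bird$n_yvad_like, 1L)           # b1 only
  expect_equal(bird$fraction_yvad_like, 1 / 3)
  rep <- out[out$clade == "reptile", ]
  expect_equal(rep$n_with_caspase1_like, 0L)
  expect_true(all(out$fraction_yvad_like >= 0 & out$fraction_yvad_like <= 1))
})

test_that("planted sites are recovered through projection end to end", {
  stats <- purrr::map_dfr(1:20, function(seed) {
    ds <- generate_dataset(small_sim_config(seed = seed))
    msa <- progressive_align(ds$records)
    ref_id <- ds$records$id[1]
    ref <- reference_boundaries(
      ref_id,
      beta11_end = ds$truth$linkers$start[1] - 1L,
      alpha5_start = ds$truth$linkers$end[1] + 1L)
    linkers <- project_boundaries(msa, ref)
    exact <- dplyr::inner_join(linkers, ds$truth$linkers,
                               by = "sequence_id", suffix = c("", "_true"))
    sites <- extract_linker_sites(msa, ds$records, ref)
    c1 <- sites[sites$site_class == "caspase1_like", ]
    truth <- ds$truth$sites
    hit <- dplyr::inner_join(
      c1, truth, by = c("sequence_id", "p1_position", "tetrapeptide"))
    tibble::tibble(
      # boundary-adjacent insertion placement is ambiguous under
      # sum-of-pairs scoring (linkers are non-homologous), so intervals
      # are checked for overlap with the truth, and the sites themselves
      # for exact recovery
      linker_overlap = mean(exact$start <= exact$end_true &
                              exact$end >= exact$start_true),
      recall = nrow(hit) / nrow(truth),
      precision = if (nrow(c1)) nrow(hit) / nrow(c1) else 1)
  })
  expect_gte(mean(stats$linker_overlap), 0.95)
  expect_gte(mean(stats$recall), 0.95)
  expect_equal(mean(stats$precision), 1)
})
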