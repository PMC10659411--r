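test_that("FASTA reading handles wrapping, metadata, and empty input", {
  f <- withr::local_tempfile(fileext = ".fasta")

  writeLines(character(0), f)
  expect_equal(nrow(read_fasta(f)), 0)

  writeLines(c(">a", "MKV", "LQ"), f)
  recs <- read_fasta(f)
  expect_equal(recs$sequence, "MKVLQ")
  expect_equal(recs$taxon, "")

  writeLines(c(">a taxon=Gallus_gallus;clade=bird", "MKVLQ",
               ">b", "WYF"), f)
  recs <- read_fasta(f)
  expect_equal(recs$taxon, c("Gallus_gallus", ""))
  expect_equal(recs$clade, c("bird", ""))
})

test_that("FASTA write then read is the identity", {
  f <- withr::local_tempfile(fileext = ".fasta")
  recs <- toy_records()
  write_fasta(recs, f, width = 4)  # force wrapping
  expect_equal(read_fasta(f), recs)
})

test_that("FASTA contract violations raise named errors", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">a", "MKV", ">a", "WY"), f)
  expect_error(read_fasta(f), "duplicate.*'a'")
  writeLines(c(">a", "MKB"), f)
  expect_error(read_fasta(f), "illegal character 'B' at position 3")
  writeLines(c(">a", ""), f)
  expect_error(read_fasta(f), "empty sequence")
})

test_that("pairwise identity uses the shorter-sequence denominator", {
  expect_equal(pairwise_identity("MKVL", "MKVL"), 1.0)
  expect_equal(pairwise_identity("MKVL", "WWWW"), 0.0)
  # frozen from exhaustive enumeration: the unique optimal alignment of
  # MKVLQ with MKV matches all three residues of the shorter sequence
  expect_equal(brute_global_score("MKVLQ", "MKV"),
               global_align("MKVLQ", "MKV")$score)
  expect_equal(pairwise_identity("MKVLQ", "MKV"), 1.0)
  expect_error(pairwise_identity("", "MKV"), "empty")
})

test_that("greedy clustering partitions records and respects the threshold", {
  recs <- toy_records()
  same <- dplyr::mutate(recs, sequence = "MKVLQAWMKVLQAW")
  cl <- greedy_cluster(same, 0.9)
  expect_equal(length(unique(cl$representative_id)), 1)
  expect_setequal(cl$member_id, same$id)

  set.seed(41)
  unrelated <- tibble::tibble(
    id = c("u1", "u2", "u3"), taxon = "", clade = "",
    sequence = c(strrep("W", 30), strrep("K", 30), strrep("P", 30)))
  expect_equal(nrow(unique(greedy_cluster(unrelated, 0.5)["representative_id"])), 3)
})

test_that("planted redundant copies collapse to the expected cluster count", {
  set.seed(7)
  base <- random_protein(60)
  mutate_at <- function(s, k) {
    ch <- strsplit(s, "")[[1]]
    idx <- sample(length(ch), k)
    ch[idx] <- vapply(ch[idx], function(c0) sample(setdiff(AA20, c0), 1), "")
    paste(ch, collapse = "")
  }
  copies <- tibble::tibble(id = sprintf("c%02d", 1:10), taxon = "", clade = "",
                           sequence = vapply(1:10, function(i) mutate_at(base, 3), ""))
  lone <- tibble::tibble(id = paste0("u", 1:5), taxon = "", clade = "",
                         sequence = vapply(1:5, function(i) random_protein(60), ""))
  recs <- dplyr::bind_rows(copies, lone)

  # oracle: all-vs-all identity matrix confirms the planted structure
  ids <- recs$id
  for (i in 1:10) expect_gte(pairwise_identity(copies$sequence[i], base), 0.9)
  for (i in 1:5) for (j in 1:10) {
    expect_lt(pairwise_identity(lone$sequence[i], copies$sequence[j]), 0.9)
  }

  cl <- greedy_cluster(recs, 0.9)
  expect_equal(length(unique(cl$representative_id)), 6)
  # partition: every input id in exactly one cluster
  expect_setequal(cl$member_id, ids)
  expect_equal(anyDuplicated(cl$member_id), 0)
})

test_that("greedy clustering is invariant to input order", {
  set.seed(11)
  recs <- tibble::tibble(id = paste0("s", 1:8), taxon = "", clade = "",
                         sequence = vapply(1:8, function(i) random_protein(40), ""))
  cl1 <- greedy_cluster(recs, 0.6)
  for (s in 1:3) {
    cl2 <- greedy_cluster(recs[sample(8), ], 0.6)
    expect_equal(dplyr::arrange(cl2, member_id), dplyr::arrange(cl1, member_id))
  }
})

test_that("reciprocal best hits pair mutual best matches only", {
  recs <- toy_records()
  pairs <- reciprocal_best_hits(recs, recs, min_score = 5)
  expect_equal(pairs$id_a, pairs$id_b)
  expect_equal(nrow(pairs), nrow(recs))

  expect_equal(nrow(reciprocal_best_hits(recs, recs[0, ])), 0)

  # asymmetric toy: a1 best-hits b1, but b1's best is a2 -> a1 excluded
  set.seed(3)
  x <- random_protein(40)
  x_mut <- sub("^(.{5}).{3}", "\\1WWW", x)
  seta <- tibble::tibble(id = c("a1", "a2"), taxon = "", clade = "",
                         sequence = c(x_mut, x))
  setb <- tibble::tibble(id = c("b1", "b2"), taxon = "", clade = "",
                         sequence = c(x, strrep("P", 40)))
  pairs <- reciprocal_best_hits(seta, setb, min_score = 20)
  expect_equal(pairs$id_a, "a2")
  expect_equal(pairs$id_b, "b1")
})

test_that("reciprocal best hits are symmetric in the two sets", {
  set.seed(9)
  seta <- tibble::tibble(id = paste0("a", 1:3), taxon = "", clade = "",
                         sequence = vapply(1:3, function(i) random_protein(50), ""))
  setb <- dplyr::mutate(seta, id = paste0("b", 1:3),
                        sequence = vapply(sequence, function(s) {
                          sub("^.{2}", "GG", s)
                        }, "", USE.NAMES = FALSE))
  p1 <- reciprocal_best_hits(seta, setb, min_score = 20)
  p2 <- reciprocal_best_hits(setb, seta, min_score = 20)
  expect_equal(p1$id_a, p2$id_b)
  expect_equal(p1$id_b, p2$id_a)
})

test_that("partial-row trimming applies the 50 percent rules strictly", {
  pad <- function(s, w) paste0(s, strrep("-", w - nchar(s)))
  msa <- new_msa(c("full", "sixty_gaps", "half_gaps"),
                 c(strrep("A", 100), pad(strrep("A", 40), 100),
                   pad(strrep("A", 50), 100)),
                 check_all_gap = FALSE)
  out <- trim_partial(msa)
  expect_setequal(out$ids, c("full", "half_gaps"))  # exactly 50% retained
  expect_equal(msa_width(out), 100)                 # column set unchanged

  ungapped <- new_msa(c("x", "y"), c("MKVL", "MKVA"))
  expect_equal(trim_partial(ungapped), ungapped)
  # idempotence
  expect_equal(trim_partial(out), out)
  all_bad <- new_msa("p", pad("A", 10), check_all_gap = FALSE)
  expect_error(trim_partial(all_bad), "empty alignment")
})
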