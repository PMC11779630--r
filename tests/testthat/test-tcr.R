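test_that("immunoSEQ-style files parse, drop non-productive rows", {
  path <- tempfile(fileext = ".tsv")
  writeLines(c("cdr3_aa\ttemplates\tframe",
               "CASSLGQAYEQYF\t60\tIn",
               "CASSPD*GSYEQYF\t10\tStop", # stop codon
               "CASSFGREQYF\t30\tIn",
               "CASSQDLNTGELFF\t10\tOut", # frame flag
               "CASSARTGELFF\t10\tIn"), path)
  expect_message(rep <- read_immunoseq(path, sample_id = "sA",
                                       patient_id = "PT1",
                                       compartment = "tumor",
                                       tissue = "primary"),
                 "2 non-productive")
  expect_equal(nrow(rep$clonotypes), 3)
  expect_equal(rep$total_productive_templates, 100)
  expect_equal(sum(rep$clonotypes$productive_frequency), 1)
  expect_equal(rep$clonotypes$productive_frequency[1], 0.6)

  empty <- tempfile(fileext = ".tsv")
  writeLines("cdr3_aa\ttemplates", empty)
  expect_error(read_immunoseq(empty), "empty")
  noisy <- tempfile(fileext = ".tsv")
  writeLines(c("sequence\tcount", "CASSF\t5"), noisy)
  expect_error(read_immunoseq(noisy), "cdr3_aa")
  # round trip through the writer
  out <- tempfile(fileext = ".tsv")
  write_immunoseq(rep, out)
  back <- read_immunoseq(out, sample_id = "sA")
  expect_equal(back$clonotypes$cdr3_aa, rep$clonotypes$cdr3_aa)
})

test_that("QC excludes repertoires under 100 productive templates", {
  cd <- fixture_cdr3(3)
  r99 <- make_rep("low", cd, c(33, 33, 33))
  r100 <- make_rep("edge", cd, c(34, 33, 33))
  kept <- qc_filter(list(r99, r100))
  expect_equal(vapply(kept, `[[`, "", "sample_id"), "edge")
  expect_length(qc_filter(list()), 0)
})

test_that("diversity metrics match hand arithmetic and conventions", {
  cd <- fixture_cdr3(4)
  uni <- diversity_metrics(make_rep("u", cd, rep(25, 4)))
  expect_equal(uni$richness, 4)
  expect_equal(uni$shannon, log(4))
  expect_equal(uni$clonality, 0)
  expect_equal(uni$simpson_d, 0.25)
  expect_equal(uni$simpson_diversity, 0.75)
  expect_equal(uni$simpson_evenness, 1)

  two <- diversity_metrics(make_rep("h", cd[1:2], c(50, 50)))
  expect_equal(two$shannon, 0.6931, tolerance = 1e-4)
  expect_equal(two$simpson_d, 0.5)

  mono <- diversity_metrics(make_rep("m", cd[1], 40))
  expect_equal(mono$clonality, 1)
  expect_equal(mono$pielou, 0)
  expect_equal(mono$simpson_diversity, 0)

  # frequency-based: uniform doubling of templates changes nothing
  a <- diversity_metrics(make_rep("a", cd, c(10, 20, 30, 40)))
  b <- diversity_metrics(make_rep("b", cd, c(20, 40, 60, 80)))
  expect_equal(a[, 5:11], b[, 5:11])
  # row order invariance
  c1 <- diversity_metrics(make_rep("c", cd[4:1], c(40, 30, 20, 10)))
  expect_equal(a$shannon, c1$shannon)
  expect_equal(a$simpson_d, c1$simpson_d)
  # templates per ng
  ng <- diversity_metrics(make_rep("n", cd[1:2], c(150, 50),
                                   input_ng = 4))
  expect_equal(ng$templates_per_ng, 50)
  expect_error(diversity_metrics(make_rep("z", character(0),
                                          integer(0))),
               "zero productive")
})

test_that("overlap and Jaccard follow set arithmetic and are symmetric", {
  A <- make_rep("A", c("CASSAF", "CASSGF", "CASSHF"), c(5, 5, 5))
  B <- make_rep("B", c("CASSGF", "CASSHF", "CASSIF"), c(7, 2, 1))
  ov <- repertoire_overlap(A, B)
  expect_equal(ov$public, 2)
  expect_equal(ov$jaccard, 0.5)
  expect_equal(repertoire_overlap(B, A), ov)
  expect_equal(repertoire_overlap(A, A)$jaccard, 1)
  D <- make_rep("D", c("CASSKF", "CASSLF"), c(1, 1))
  expect_equal(repertoire_overlap(A, D)$public, 0)
  expect_equal(repertoire_overlap(A, D)$jaccard, 0)
  E0 <- make_rep("E", character(0), integer(0))
  expect_warning(ov0 <- repertoire_overlap(E0, E0), "empty")
  expect_equal(ov0$jaccard, 0)
})

test_that("mean pairwise overlap averages hand-computed Jaccards", {
  A <- make_rep("A", c("CASSAF", "CASSGF"), c(1, 1))
  B1 <- make_rep("B1", c("CASSAF", "CASSGF", "CASSHF", "CASSIF"),
                 rep(1, 4)) # jaccard 2/4 = 0.5
  # jaccard(A, B2) = 0.2: |intersection| = 1, |union| = 5
  B2 <- make_rep("B2", c("CASSAF", "CASSMF", "CASSNF", "CASSPF"),
                 rep(1, 4))
  mo <- mean_pairwise_overlap(A, list(B1, B2))
  expect_equal(mo$mean_jaccard, 0.35)
  expect_equal(mo$mean_public, 1.5)
  # two copies of the query itself: mean Jaccard is exactly one
  expect_equal(mean_pairwise_overlap(A, list(A, A))$mean_jaccard, 1)
  # fully disjoint comparisons: both means are zero
  C1 <- make_rep("C1", c("CASSQF", "CASSRF"), c(1, 1))
  expect_equal(mean_pairwise_overlap(A, list(C1)),
               list(mean_public = 0, mean_jaccard = 0))
  expect_error(mean_pairwise_overlap(A, list()), "no comparison")
})

test_that("tumor-distinct percent follows the combined-template rule", {
  tumor <- make_rep("t", c("CASSTF", "CASSVF", "CASSWF"), c(12, 5, 20),
                    compartment = "tumor", tissue = "primary")
  blood <- make_rep("b", c("CASSTF", "CASSQF"), c(12, 30))
  pair <- repertoire_pair(blood, tumor)
  # universe {T:24, W:20, Q:30}; tumor-distinct {W}
  expect_equal(tumor_distinct_percent(pair), 100 / 3, tolerance = 1e-9)

  # tumor subset of blood -> 0%
  t2 <- make_rep("t2", c("CASSTF", "CASSQF"), c(15, 10),
                 compartment = "tumor", tissue = "primary")
  b2 <- make_rep("b2", c("CASSTF", "CASSQF", "CASSRF"), c(15, 10, 40))
  expect_equal(tumor_distinct_percent(repertoire_pair(b2, t2)), 0)

  # blood effectively absent -> 100%
  t3 <- make_rep("t3", "CASSMF", 11, compartment = "tumor",
                 tissue = "primary")
  b3 <- make_rep("b3", "CASSNF", 3)
  expect_equal(tumor_distinct_percent(repertoire_pair(b3, t3)), 100)

  # nothing reaches 10 combined templates -> NA with warning
  t4 <- make_rep("t4", "CASSSF", 4, compartment = "tumor",
                 tissue = "primary")
  b4 <- make_rep("b4", "CASSTF", 3)
  expect_warning(res <- tumor_distinct_percent(repertoire_pair(b4, t4)),
                 "combined templates")
  expect_true(is.na(res))
  expect_error(repertoire_pair(b4, make_rep("x", "CASSSF", 4,
                                            patient = "PT9",
                                            compartment = "tumor",
                                            tissue = "primary")),
               "different patients")
})

test_that("shared dominant clones apply the top-50 / 25% rule", {
  # 10 samples: one ubiquitous dominant clone + 60 private clones each
  cds <- fixture_cdr3(600)
  cohort <- lapply(1:10, function(i) {
    own <- cds[((i - 1) * 60 + 1):(i * 60)]
    make_rep(paste0("s", i), c("CASSDMF", own), c(500, rep(5, 60)),
             patient = paste0("PT", i))
  })
  expect_equal(shared_dominant_clones(cohort), "CASSDMF")

  # present everywhere but never in any top 50 -> excluded
  cohort2 <- lapply(1:4, function(i) {
    own <- cds[((i - 1) * 60 + 1):(i * 60)]
    make_rep(paste0("s", i), c(own, "CASSRAREF"), c(rep(100, 60), 1),
             patient = paste0("PT", i))
  })
  expect_false("CASSRAREF" %in% shared_dominant_clones(cohort2))

  # 25% boundary inclusive: top-50 clone of one sample, present in
  # exactly 1 of 4 samples (ceiling(0.25 * 4) = 1)
  solo <- make_rep("solo", c("CASSNEF", cds[1:10]), c(50, rep(1, 10)))
  others <- lapply(1:3, function(i)
    make_rep(paste0("o", i), cds[20:29], rep(10, 10)))
  expect_true("CASSNEF" %in% shared_dominant_clones(c(list(solo),
                                                       others)))

  # ties at rank 50 are all included: 1 big + 51 tied clones
  tied <- make_rep("tied", c("CASSHIGF", cds[101:151]),
                   c(1000, rep(10, 51)))
  got <- shared_dominant_clones(list(tied), top_n = 50,
                                min_prevalence = 0.25)
  expect_length(got, 52)
  expect_error(shared_dominant_clones(list()), "empty")
})

test_that("per-patient shared-clone burden counts and sums frequencies", {
  shared <- c("CASSAF", "CASSGF", "CASSHF")
  rep1 <- make_rep("r1", c("CASSAF", "CASSGF", "CASSHF", "CASSIF"),
                   c(1, 2, 3, 94))
  st <- per_patient_shared_stats(list(rep1), shared)
  expect_equal(st$count, 3)
  expect_equal(st$total_freq, 0.06)
  expect_equal(per_patient_shared_stats(list(rep1), character(0)),
               list(count = 0L, total_freq = 0))
  none <- make_rep("r2", "CASSWF", 10)
  expect_equal(per_patient_shared_stats(list(none), shared)$count, 0)
  # multiple samples: counts pool, frequencies average
  rep2 <- make_rep("r3", c("CASSAF", "CASSEF"), c(10, 90))
  st2 <- per_patient_shared_stats(list(rep1, rep2), shared)
  expect_equal(st2$count, 3)
  expect_equal(st2$total_freq, mean(c(0.06, 0.1)))
})

test_that("expanded clones require > 1 template per patient on average", {
  mk <- function(id, pt, tpl)
    make_rep(id, names(tpl), unname(tpl), patient = pt,
             compartment = "tumor", tissue = "primary")
  tums <- list(
    mk("t1", "P1", c(CASSAF = 2, CASSEF = 1, CASSCF = 1)),
    mk("t2", "P2", c(CASSAF = 1, CASSEF = 1)),
    mk("t3", "P3", c(CASSAF = 1, CASSEF = 1)))
  got <- expanded_clones(tums)
  # A totals 4 across 3 patients (4/3 > 1): expanded;
  # B totals exactly 3 (3/3, strict >): not expanded
  expect_equal(got, "CASSAF")
  expect_equal(expanded_clones(list(mk("t", "P1", c(CASSGF = 2)))),
               "CASSGF")
  expect_length(expanded_clones(list(mk("t", "P1", c(CASSGF = 1)))), 0)
  expect_error(expanded_clones(list()), "empty")
})

test_that("reference CDR3 matching is exact, deduplicated, frequency-aware", {
  ref_path <- system.file("extdata", "synthetic_kras_cdr3.txt",
                          package = "organotrope")
  ref <- read_reference_cdr3(ref_path)
  expect_length(ref, 21)
  rep1 <- make_rep("r", c(ref[1], ref[2], "CASSNPEF"), c(10, 30, 60))
  m <- match_reference_cdr3(rep1, ref)
  expect_equal(m$n_matched, 2)
  expect_equal(unname(m$matched_freqs), c(0.1, 0.3))
  expect_equal(match_reference_cdr3(rep1, c(ref, ref))$n_matched, 2)
  none <- make_rep("n", "CASSNPEF", 5)
  expect_equal(match_reference_cdr3(none, ref)$n_matched, 0)
  expect_length(match_reference_cdr3(none, ref)$matched_freqs, 0)
  expect_error(match_reference_cdr3(rep1, character(0)), "empty")
})

test_that("blood samples classify against the disease timeline", {
  # resected: on the day of resection counts as primary-associated
  expect_equal(classify_blood_sample(100, resection_day = 100,
                                     resected = TRUE),
               "primary_associated")
  expect_equal(classify_blood_sample(99, resection_day = 100,
                                     resected = TRUE),
               "primary_associated")
  expect_equal(classify_blood_sample(410, resection_day = 100,
                                     recurrence_day = 400,
                                     resected = TRUE),
               "metastasis_associated")
  expect_equal(classify_blood_sample(200, resection_day = 100,
                                     recurrence_day = 400,
                                     resected = TRUE),
               "uncharacterized")
  # non-resected: within 30 days before detection is metastasis-assoc.
  expect_equal(classify_blood_sample(480, met_detected_day = 500,
                                     resected = FALSE),
               "metastasis_associated")
  expect_equal(classify_blood_sample(600, met_detected_day = 500,
                                     resected = FALSE),
               "metastasis_associated")
  # within 180 days before last confirmed met-free date
  expect_equal(classify_blood_sample(30, last_met_free_day = 200,
                                     resected = FALSE),
               "primary_associated")
  expect_equal(classify_blood_sample(10, last_met_free_day = 300,
                                     resected = FALSE),
               "uncharacterized")
  expect_error(classify_blood_sample(10, resection_day = 200,
                                     recurrence_day = 100,
                                     resected = TRUE),
               "contradictory")
})
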