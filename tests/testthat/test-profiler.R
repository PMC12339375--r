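# Profiler: query, winner-take-all reassignment, abundances, detection.

pp <- sketch_params(k = 31, c = 1)

# Fixture: sample in which genome k-mers appear at a fixed multiplicity.
flat_sample <- function(hashes, mult, total_bases = 4e6) {
  make_sample_sketch(hashes, rep(mult, length(hashes)), pp,
                     total_bases = total_bases)
}

test_that("query estimates genomes independently and sorts by ANI", {
  gh <- seq_len(300)
  gA <- make_genome_sketch(gh, pp, id = "A")
  gB <- make_genome_sketch(gh, pp, id = "B")  # identical sketch, other id
  s <- flat_sample(gh, 8)
  em <- estimate_error_term(s, 0)
  ests <- query_sample(list(gB, gA), s, error_model = em, seed = 1)
  expect_equal(vapply(ests, `[[`, character(1), "genome_id"), c("A", "B"))
  expect_equal(ests[[1]]$adjusted_ani, ests[[2]]$adjusted_ani)
  expect_equal(ests[[1]]$n_contained, ests[[2]]$n_contained)
  expect_length(query_sample(list(), s, error_model = em), 0L)
})

test_that("winner-take-all assigns shared k-mers to the top-ANI genome", {
  gh <- seq_len(300)
  gA <- make_genome_sketch(gh, pp, id = "A")
  gB <- make_genome_sketch(gh, pp, id = "B")
  s <- flat_sample(gh, 2)
  hists <- reassign_kmers(list(gA, gB), s, c(A = 0.99, B = 0.97))
  expect_equal(hists[["A"]]$n_contained, 300L)
  expect_equal(hists[["B"]]$n_contained, 0L)
  expect_equal(hists[["B"]]$n_sketch_kmers, 300L)  # N unchanged
  expect_equal(attr(hists[["A"]], "n_kmers_reassigned"), 300L)
  # ties break lexicographically
  hists_tie <- reassign_kmers(list(gA, gB), s, c(A = 0.99, B = 0.99))
  expect_equal(hists_tie[["A"]]$n_contained, 300L)
  expect_equal(hists_tie[["B"]]$n_contained, 0L)
})

test_that("disjoint genomes are untouched by reassignment", {
  gA <- make_genome_sketch(1:100, pp, id = "A")
  gB <- make_genome_sketch(201:300, pp, id = "B")
  s <- flat_sample(c(1:100, 201:300), 3)
  hists <- reassign_kmers(list(gA, gB), s, c(A = 0.99, B = 0.97))
  expect_equal(hists[["A"]]$n_contained, 100L)
  expect_equal(hists[["B"]]$n_contained, 100L)
  expect_equal(attr(hists[["A"]], "n_kmers_reassigned"), 0L)
})

test_that("reassignment equals brute-force per-k-mer argmax on a toy case", {
  # 20 k-mers, three genomes with partial overlaps
  kA <- 1:12; kB <- 7:16; kC <- c(3:5, 13:20)
  ani <- c(A = 0.97, B = 0.99, C = 0.96)
  gA <- make_genome_sketch(kA, pp, id = "A")
  gB <- make_genome_sketch(kB, pp, id = "B")
  gC <- make_genome_sketch(kC, pp, id = "C")
  s <- flat_sample(1:20, 1)
  hists <- reassign_kmers(list(gA, gB, gC), s, ani)
  # brute force: per k-mer, owner = genome with max ANI among holders
  owner <- vapply(1:20, function(k) {
    holders <- c("A", "B", "C")[c(k %in% kA, k %in% kB, k %in% kC)]
    holders[order(-ani[holders], holders)][1]
  }, character(1))
  for (id in c("A", "B", "C")) {
    km <- list(A = kA, B = kB, C = kC)[[id]]
    expect_equal(hists[[id]]$n_contained, sum(owner[km] == id), info = id)
  }
  # conservation: every sample k-mer found in >= 1 genome assigned once
  total <- sum(vapply(hists, `[[`, integer(1), "n_contained"))
  expect_equal(total, length(unique(c(kA, kB, kC))))
})

test_that("reassignment never increases containment", {
  set.seed(77)
  for (i in 1:10) {
    ks <- lapply(1:4, function(j) sample(1:400, 150))
    gs <- lapply(1:4, function(j)
      make_genome_sketch(ks[[j]], pp, id = LETTERS[j]))
    s <- flat_sample(1:400, 2)
    before <- vapply(gs, function(g)
      build_histogram(g, s)$n_contained, integer(1))
    ani <- setNames(runif(4, 0.9, 1), LETTERS[1:4])
    hists <- reassign_kmers(gs, s, ani)
    after <- vapply(LETTERS[1:4], function(id)
      hists[[id]]$n_contained, integer(1))
    expect_true(all(after <= before))
    expect_equal(sum(after), length(unique(unlist(ks))))
  }
})

test_that("profile abundances follow the lambda and lambda*GL formulas", {
  # genome A at effective coverage 4, genome B at 12 (m > 3: median branch,
  # so coverages are exact and abundances are closed-form)
  gA <- make_genome_sketch(1:2000, pp, id = "A", genome_length = 2e6)
  gB <- make_genome_sketch(3001:5000, pp, id = "B", genome_length = 1e6)
  s <- make_sample_sketch(c(1:2000, 3001:5000),
                          c(rep(4, 2000), rep(12, 2000)), pp,
                          total_bases = 4e7)
  em <- estimate_error_term(s, 0)
  rep_ <- profile_sample(list(gA, gB), s, error_model = em, seed = 1)
  rec <- rep_$records
  expect_equal(nrow(rec), 2L)
  expect_equal(rec$taxonomic_abundance[rec$genome == "A"], 100 * 4 / 16)
  expect_equal(rec$taxonomic_abundance[rec$genome == "B"], 100 * 12 / 16)
  # sequence abundance weights by genome length: 4*2 vs 12*1
  expect_equal(rec$sequence_abundance[rec$genome == "A"], 100 * 8 / 20)
  expect_equal(rec$sequence_abundance[rec$genome == "B"], 100 * 12 / 20)
  expect_equal(sum(rec$taxonomic_abundance), 100, tolerance = 1e-9)
  expect_equal(sum(rec$sequence_abundance), 100, tolerance = 1e-9)
  # percent reads detected: sum(delta*GL)/total, delta = lambda*150/120
  delta <- c(4, 12) * 150 / 120
  prd_exp <- min(100, 100 * sum(delta * c(2e6, 1e6)) / 4e7)
  expect_equal(rep_$percent_reads_detected, prd_exp)
  # unknown scaling multiplies both columns by prd/100
  rep_u <- profile_sample(list(gA, gB), s, error_model = em,
                          unknown_scaling = TRUE, seed = 1)
  expect_equal(sum(rep_u$records$taxonomic_abundance),
               rep_u$percent_reads_detected, tolerance = 1e-9)
})

test_that("percent_reads_detected follows the capped formula", {
  expect_equal(percent_reads_detected(2, 1e6, 4e6), 50)
  expect_equal(percent_reads_detected(c(10, 10), c(1e6, 1e6), 4e6), 100)
  expect_equal(percent_reads_detected(numeric(0), numeric(0), 4e6), 0)
})

test_that("the 95% threshold excludes a 90%-ANI relative", {
  p <- sketch_params()
  g <- random_genome(8e5, seed = 66)
  rel <- mutate_genome(g, theta = 0.10, seed = 67)$sequence
  gs <- sketch_genome(g, p, genome_id = "target")
  gs_rel <- sketch_genome(rel, p, genome_id = "relative")
  rr <- sample_reads(g, 3, L = 150, seed = 68)
  ss <- sketch_reads(rr$reads1, params = p, dedup = FALSE)
  em <- estimate_error_term(ss, 0)
  rep_ <- profile_sample(list(gs, gs_rel), ss, error_model = em, seed = 2)
  expect_equal(rep_$records$genome, "target")
  expect_gte(rep_$records$adjusted_ani[1], 0.99)
  # no genome passes -> empty report, prd 0
  none <- profile_sample(list(gs_rel), ss, error_model = em, seed = 2,
                         min_ani = 0.999)
  expect_equal(nrow(none$records), 0L)
  expect_equal(none$percent_reads_detected, 0)
})

test_that("profiling is deterministic given the seed", {
  p <- sketch_params()
  g <- random_genome(3e5, seed = 70)
  gs <- sketch_genome(g, p, genome_id = "g")
  rr <- sample_reads(g, delta_for_lambda(0.8, 150, 31), L = 150, seed = 71)
  ss <- sketch_reads(rr$reads1, params = p, dedup = FALSE)
  em <- estimate_error_term(ss, 0)
  r1 <- profile_sample(list(gs), ss, error_model = em, seed = 5)
  r2 <- profile_sample(list(gs), ss, error_model = em, seed = 5)
  expect_identical(r1, r2)
})
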