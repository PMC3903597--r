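test_that("reference transposase is deterministic with the contract architecture", {
  r1 <- make_reference_transposase(1)
  r2 <- make_reference_transposase(1)
  expect_identical(r1, r2)
  expect_false(identical(r1$protein, make_reference_transposase(2)$protein))
  aa <- strsplit(r1$protein, "")[[1]]
  expect_identical(aa[r1$dde], c("D", "D", "E"))
  expect_gt(r1$dde[3] - r1$dde[1], 100)               # catalytic span rule
  hth_len <- r1$hth[2] - r1$hth[1] + 1
  expect_true(hth_len >= 20 && hth_len <= 60)
  expect_false(any(aa[2:31] == "M"))                  # start-scan window clean
})

test_that("planted elements carry the requested structure and defects", {
  set.seed(5)
  el <- plant_mule(cfg_fix, character(), ref = ref_fix)
  expect_true(nchar(el$seq) >= 2000 && nchar(el$seq) <= 30000)
  expect_true(nchar(el$tsd) >= 8 && nchar(el$tsd) <= 11)
  tr <- el$truth
  tirL <- substr(el$seq, tr$tirL[1], tr$tirL[2])
  tirR_rc <- mulescan:::revcomp(substr(el$seq, tr$tirR[1], tr$tirR[2]))
  ident <- mean(strsplit(tirL, "")[[1]] == strsplit(tirR_rc, "")[[1]])
  expect_lt(abs(ident - cfg_fix$tir_identity), 0.02)
  # planted CDS translates back to the reference protein
  cds <- substr(el$seq, tr$cds[1], tr$cds[2])
  expect_identical(substr(mulescan:::translate_dna(cds), 1, 800), ref_fix$protein)

  el2 <- plant_mule(cfg_fix, "premature_stop", ref = ref_fix)
  cds2 <- substr(el2$seq, el2$truth$cds[1], el2$truth$cds[2])
  aa2 <- mulescan:::translate_dna(substr(cds2, 1, nchar(cds2) - 3))
  expect_identical(sum(strsplit(aa2, "")[[1]] == "*"), 1L)  # exactly one planted stop
  el3 <- plant_mule(cfg_fix, c("frameshift", "deletion"), ref = ref_fix)
  expect_setequal(el3$truth$defects, c("frameshift", "deletion"))
  expect_named(el3$truth$defect_detail, c("deletion", "frameshift"))
})

test_that("nested LTR retroelements age as 2rT expects", {
  set.seed(8)
  el <- plant_mule(cfg_fix, character(), ref = ref_fix)
  young <- insert_nested_te(el, "LTR_retro", target_age_myr = 0)
  ins <- young$truth$insertions[[1]]
  expect_identical(ins$ltr5, ins$ltr3)                # age 0: identical LTRs
  # mean realized divergence over replicates approaches 2 * r * T
  reps <- replicate(120, {
    e <- insert_nested_te(el, "LTR_retro", target_age_myr = 1)
    i <- e$truth$insertions[[1]]
    sum(strsplit(i$ltr5, "")[[1]] != strsplit(i$ltr3, "")[[1]]) / nchar(i$ltr5)
  })
  expect_lt(abs(mean(reps) - 0.026), 0.1 * 0.026)     # within 10% of 2rT
  mite <- insert_nested_te(el, "MITE")
  expect_identical(mite$truth$insertions[[1]]$length, 274L)
  expect_identical(mite$truth$insertions[[1]]$te_class, "DNA")
})

test_that("nested insertions conserve sequence length and coordinates", {
  set.seed(9)
  el <- plant_mule(cfg_fix, character(), ref = ref_fix)
  before <- nchar(el$seq)
  el2 <- insert_nested_te(el, "DNA_TE")
  ins <- el2$truth$insertions[[1]]
  expect_identical(nchar(el2$seq), before + ins$length + nchar(ins$tsd))
  # the recorded interval really contains the TE (flanked by the TSD copies)
  expect_identical(substr(el2$seq, ins$excise[2] - nchar(ins$tsd) + 1L, ins$excise[2]),
                   ins$tsd)
  # CDS coordinates still point at transposase sequence
  cds <- substr(el2$seq, el2$truth$cds[1], el2$truth$cds[1] + 29L)
  expect_identical(mulescan:::translate_dna(cds),
                   substr(ref_fix$protein, 1, 10))
})

test_that("simulated genomes are deterministic and internally consistent", {
  cfg <- sim_config(seed = 11, genome_len = 60000, n_elements = 3)
  s1 <- simulate_genome(cfg)
  s2 <- simulate_genome(cfg)
  expect_identical(s1$genome, s2$genome)
  expect_identical(s1$truth, s2$truth)
  # planted coordinates validate against the emitted genome
  for (id in names(s1$truth)) {
    tr <- s1$truth[[id]]
    expect_identical(substr(s1$genome[[1]], tr$span[1], tr$span[2]),
                     tr$element_seq)
    expect_identical(substr(s1$genome[[1]], tr$span[1] - nchar(tr$tsd),
                            tr$span[1] - 1L), tr$tsd)
    expect_identical(substr(s1$genome[[1]], tr$span[2] + 1L,
                            tr$span[2] + nchar(tr$tsd)), tr$tsd)
  }
  expect_lte(sum(sapply(s1$truth, function(x) diff(x$span) + 1)),
             cfg$genome_len)
  s0 <- simulate_genome(sim_config(seed = 2, genome_len = 30000, n_elements = 0))
  expect_identical(nrow(s0$annotations), 0L)
  expect_error(simulate_genome(sim_config(seed = 2, genome_len = 9000,
                                          n_elements = 4)),
               "too small")
})

test_that("homolog mutation realizes the configured rates", {
  set.seed(13)
  base <- random_seq(10000)
  same <- mutate_homolog(base, 0, 0)
  expect_identical(same$seq, base)
  m <- mutate_homolog(base, 0.02, 0)
  expect_lt(abs(m$truth$n_sub - 200), 3 * sqrt(10000 * 0.02 * 0.98))
  # Poisson mean of indel events over replicates
  counts <- replicate(200, mutate_homolog(random_seq(5000), 0, 2)$truth$n_indels)
  expect_lt(abs(mean(counts) - 10), 3 * sqrt(10 / 200))
})

test_that("simulated ESTs are traceable substrings of their elements", {
  set.seed(17)
  els <- c(e1 = random_seq(4000), e2 = random_seq(5000))
  sim <- simulate_est_records(els, 25)
  expect_identical(length(sim$ests), 25L)
  for (i in seq_len(25)) {
    tr <- sim$truth[i, ]
    expect_identical(sim$ests[[tr$est_id]],
                     substr(els[[tr$element_id]], tr$start, tr$start + tr$len - 1L))
    expect_true(tr$len >= 300 && tr$len <= 1500)
  }
})
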