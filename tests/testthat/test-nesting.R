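make_nested_sim <- function(seed = 41, n = 4, rate = 2) {
  cfg <- sim_config(seed = seed, genome_len = 40000 + n * 12000, n_elements = n,
                    nested_rate = rate)
  simulate_genome(cfg)
}

test_that("nested insertions are detected with class and length from annotations", {
  sim <- make_nested_sim()
  calls_needed <- FALSE
  for (id in names(sim$truth)) {
    tr <- sim$truth[[id]]
    el <- data.frame(id = id, seq_id = "synth_chr1", start = tr$span[1],
                     end = tr$span[2], tir_left_end = tr$tirL[2],
                     tir_right_start = tr$tirR[1], stringsAsFactors = FALSE)
    ins <- detect_nested_insertions(el, sim$annotations)
    expect_identical(nrow(ins), length(tr$insertions))
    if (length(tr$insertions)) {
      calls_needed <- TRUE
      got <- ins[order(ins$start), ]
      planted <- tr$insertions[order(sapply(tr$insertions, function(x) x$interval[1]))]
      for (k in seq_along(planted)) {
        expect_identical(got$te_class[k], planted[[k]]$te_class)
        # the planted interval, not the TE's own length: a stacked insertion
        # inside a nested TE widens its footprint
        expect_identical(got$length[k],
                         as.integer(diff(planted[[k]]$interval) + 1L))
      }
    }
  }
  expect_true(calls_needed)  # the fixture actually exercised insertions
})

test_that("fragmented annotations of one insertion merge into one event", {
  el <- data.frame(id = "x", seq_id = "c", start = 1000L, end = 9000L,
                   tir_left_end = 1200L, tir_right_start = 8800L,
                   stringsAsFactors = FALSE)
  ann <- data.frame(seq_id = "c",
                    start = c(3000L, 3540L, 5000L),
                    end = c(3500L, 4000L, 5300L),
                    family = c("Copia9", "Copia9", "Copia9"),
                    te_class = "RNA", strand = "+", stringsAsFactors = FALSE)
  ins <- detect_nested_insertions(el, ann, own_family = "MULE")
  expect_identical(nrow(ins), 2L)                 # 40-bp gap merges, 1-kb gap not
  expect_identical(ins$length[1], 1001L)
})

test_that("insertion patterns classify by member TE classes", {
  mk <- function(classes) data.frame(te_class = classes, stringsAsFactors = FALSE)
  expect_identical(classify_insertion_pattern(mk("RNA"))$category, "RNA-TE")
  expect_identical(classify_insertion_pattern(mk(c("RNA", "DNA")))$category, "RNA-DNA-TE")
  expect_identical(classify_insertion_pattern(mk(c("DNA", "DNA")))$category, "DNA-TE")
  expect_identical(classify_insertion_pattern(mk(character()))$category, "none")
})

test_that("coding disruption is any overlap with the coding interval", {
  cds <- c(2000L, 4400L)
  expect_true(insertion_disrupts_coding(list(start = 2500L, end = 3000L), cds))
  expect_true(insertion_disrupts_coding(list(start = 4300L, end = 5600L), cds))
  expect_false(insertion_disrupts_coding(list(start = 100L, end = 220L), cds))
  expect_false(insertion_disrupts_coding(list(start = 6900L, end = 7200L), cds))
  expect_warning(r <- insertion_disrupts_coding(list(start = 1L, end = 2L), NULL))
  expect_false(r)
})

test_that("stripping excises insertions, conserves length and round-trips", {
  set.seed(43)
  for (rep in 1:3) {
    el <- plant_mule(cfg_fix, character(), ref = ref_fix)
    before <- el$seq
    el <- insert_nested_te(el, "LTR_retro", target_age_myr = 1)
    el <- insert_nested_te(el, "MITE")
    tr <- el$truth
    ins <- merge_insertion_intervals(do.call(rbind, lapply(tr$insertions, function(x)
      data.frame(start = x$interval[1], end = x$interval[2],
                 excise_start = x$excise[1], excise_end = x$excise[2]))))
    stripped <- strip_nested(el$seq, ins)
    expect_identical(nchar(el$seq),
                     nchar(stripped$seq) + sum(ins$excise_end - ins$excise_start + 1L))
    expect_identical(stripped$seq, before)   # reproduces the pre-insertion element
    # coordinate maps are mutually inverse on kept positions
    pos <- c(1L, tr$tirL[2], nchar(el$seq))
    sp <- map_to_stripped(pos, stripped$segments)
    expect_identical(map_to_original(sp, stripped$segments), pos)
    # excised positions have no stripped-space image
    expect_identical(map_to_stripped(ins$start[1], stripped$segments),
                     NA_integer_)
  }
  no_ins <- strip_nested("ACGTACGT", data.frame(start = integer(), end = integer()))
  expect_identical(no_ins$seq, "ACGTACGT")
})

test_that("overlapping unmerged insertions are rejected", {
  expect_error(strip_nested(strrep("ACGT", 100),
                            data.frame(start = c(10L, 50L), end = c(60L, 90L))),
               "overlapping")
})

test_that("insertion preference counts nesting directions with RNA/DNA ratio", {
  sim <- make_nested_sim(seed = 47, n = 4, rate = 1.5)
  els <- do.call(rbind, lapply(names(sim$truth), function(id) {
    tr <- sim$truth[[id]]
    data.frame(id = id, seq_id = "synth_chr1", start = tr$span[1],
               end = tr$span[2], tir_left_end = tr$tirL[2],
               tir_right_start = tr$tirR[1], stringsAsFactors = FALSE)
  }))
  pref <- insertion_preference(els, sim$annotations)
  # expected events: planted insertions after merging same-family intervals
  # within the 50-bp fragment window (stacked same-family TEs count once)
  planted_events <- function(tr, cls) {
    ins <- Filter(function(i) i$te_class == cls, tr$insertions)
    if (!length(ins)) return(0L)
    by_fam <- split(ins, vapply(ins, `[[`, "", "family"))
    sum(vapply(by_fam, function(g) {
      iv <- do.call(rbind, lapply(g, `[[`, "interval"))
      iv <- iv[order(iv[, 1]), , drop = FALSE]
      sum(c(TRUE, iv[-1, 1] > cummax(iv[, 2])[-nrow(iv)] + 50L))
    }, 0))
  }
  planted_rna <- sum(vapply(sim$truth, planted_events, 0, cls = "RNA"))
  planted_dna <- sum(vapply(sim$truth, planted_events, 0, cls = "DNA"))
  ev <- pref$events
  expect_equal(ev$rna[ev$direction == "nested_te_in_element"], planted_rna)
  expect_equal(ev$dna[ev$direction == "nested_te_in_element"], planted_dna)
  # standalone elements are not counted as inserted into other TEs
  expect_identical(ev$rna[ev$direction == "element_into_te"], 0L)
  expect_true(is.na(ev$rna_dna_ratio[ev$direction == "element_into_te"]))
})

test_that("nested summary reports per-class counts and mean lengths", {
  ins <- list(data.frame(host_id = "a", start = 1L, end = 5000L, family = "C",
                         te_class = "RNA", length = 5000L),
              data.frame(host_id = "b", start = 1L, end = 274L, family = "M",
                         te_class = "DNA", length = 274L))
  s <- nested_summary(ins)
  expect_identical(s$n, c(1L, 1L))
  expect_equal(s$mean_length, c(5000, 274))
  empty <- nested_summary(list())
  expect_identical(empty$n, c(0L, 0L))
})
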