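# Synthetic genomes with planted MULEs and machine-readable ground truth.
#
# All generator functions draw from R's global RNG; entry points that take a
# `seed` isolate their stream with with_seed() so a fixed seed gives
# bit-identical output.

DEFECT_KINDS <- c("intact", "dde_mut", "start_mut", "frameshift",
                  "premature_stop", "deletion")

#' Simulation configuration
#'
#' Defaults describe the structural envelope of TIR-MULEs: long TIRs
#' (100-500 bp) at high pairwise identity, 8-11 bp TSDs, a transposase CDS
#' between the TIRs, elements 2-30 kb overall.
#'
#' @param seed integer root seed.
#' @param genome_len background genome length in bp.
#' @param gc background GC fraction.
#' @param n_elements number of MULEs to plant.
#' @param tir_len_range TIR length range in bp.
#' @param tir_identity planted TIR pairwise identity (must exceed 0.75).
#' @param tsd_len_range TSD length range in bp.
#' @param defect_spectrum named probabilities over
#'   \code{intact, dde_mut, start_mut, frameshift, premature_stop, deletion};
#'   must sum to 1. One defect kind is drawn per element.
#' @param nested_rate mean nested insertions per element (Poisson).
#' @param nested_class_mix fraction of nested insertions that are RNA
#'   (LTR retroelement) rather than DNA (MITE or other DNA TE).
#' @param ltr_age_range age range (Myr) for nested LTR retroelements.
#' @param homolog_sub_rate substitutions per site for [mutate_homolog()].
#' @param homolog_indel_rate indel events per kb for [mutate_homolog()].
#' @param indel_len_geom_p geometric length parameter for indels.
#' @return a validated list of class \code{"sim_config"}.
#' @export
sim_config <- function(seed = 1, genome_len = 500000L, gc = 0.44,
                       n_elements = 50L,
                       tir_len_range = c(100L, 500L), tir_identity = 0.90,
                       tsd_len_range = c(8L, 11L),
                       defect_spectrum = c(intact = 1, dde_mut = 0, start_mut = 0,
                                           frameshift = 0, premature_stop = 0,
                                           deletion = 0),
                       nested_rate = 0, nested_class_mix = 0.7,
                       ltr_age_range = c(0.2, 3),
                       homolog_sub_rate = 0.02, homolog_indel_rate = 2,
                       indel_len_geom_p = 0.3) {
  stopifnot(tir_identity > 0.75, tir_identity <= 1,
            all(names(defect_spectrum) %in% DEFECT_KINDS),
            nested_rate >= 0, homolog_sub_rate >= 0, homolog_indel_rate >= 0,
            indel_len_geom_p > 0, indel_len_geom_p < 1)
  if (abs(sum(defect_spectrum) - 1) > 1e-9) stop("defect_spectrum must sum to 1")
  structure(list(seed = as.integer(seed), genome_len = as.integer(genome_len),
                 gc = gc, n_elements = as.integer(n_elements),
                 tir_len_range = as.integer(tir_len_range),
                 tir_identity = tir_identity,
                 tsd_len_range = as.integer(tsd_len_range),
                 defect_spectrum = defect_spectrum,
                 nested_rate = nested_rate, nested_class_mix = nested_class_mix,
                 ltr_age_range = ltr_age_range,
                 homolog_sub_rate = homolog_sub_rate,
                 homolog_indel_rate = homolog_indel_rate,
                 indel_len_geom_p = indel_len_geom_p),
            class = "sim_config")
}

# Apply one planted defect to a CDS string; returns list(cds, detail).
# `avoid` lists aa positions already carrying another planted defect, so a
# deletion cannot erase it (planted defects stay independently observable).
apply_defect <- function(cds, label, ref, avoid = integer()) {
  n_codon <- nchar(cds) %/% 3L
  detail <- list(label = label)
  if (label == "dde_mut") {
    pos <- sample(ref$dde, 1)
    new_codon <- if (pos == ref$dde[3]) "AAA" else "AAT"  # E->K or D->N
    substr(cds, 3 * pos - 2, 3 * pos) <- new_codon
    detail$aa_pos <- pos
  } else if (label == "start_mut") {
    substr(cds, 1, 3) <- "CTG"
  } else if (label == "premature_stop") {
    pos <- sample(round(0.15 * REF_LEN):round(0.85 * REF_LEN), 1)
    substr(cds, 3 * pos - 2, 3 * pos) <- "TAA"
    detail$aa_pos <- pos
  } else if (label == "deletion") {
    k <- sample(40:150, 1)          # aa deleted (multiple of 3 nt: no frameshift)
    if (k >= n_codon - 1) stop("deletion longer than CDS")
    starts <- seq(round(0.05 * REF_LEN), round(0.9 * REF_LEN) - k)
    if (length(avoid))
      starts <- starts[vapply(starts, function(s) !any(avoid >= s - 3 & avoid <= s + k + 2), TRUE)]
    if (!length(starts)) stop("no deletion placement avoids other planted defects")
    s <- sample(starts, 1)
    cds <- paste0(substr(cds, 1, 3 * (s - 1)), substr(cds, 3 * (s + k - 1) + 1, nchar(cds)))
    detail$aa_span <- c(s, s + k - 1)
  } else if (label == "frameshift") {
    p <- sample(round(0.2 * nchar(cds)):round(0.8 * nchar(cds)), 1)
    if (stats::runif(1) < 0.5) {
      cds <- paste0(substr(cds, 1, p - 1), substr(cds, p + 1, nchar(cds)))  # 1-nt deletion
      detail$kind <- "del1"
    } else {
      cds <- paste0(substr(cds, 1, p), sample(DNA_BASES, 1), substr(cds, p + 1, nchar(cds)))
      detail$kind <- "ins1"
    }
    detail$nt_pos <- p
  } else if (label != "intact") stop("unknown defect label: ", label)
  list(cds = cds, detail = detail)
}

#' Plant one MULE with chosen coding defects
#'
#' Builds \code{TIR + pad + transposase CDS (with requested defects) + pad +
#' revcomp(TIR')} plus a TSD string for the flanks. The right TIR is the
#' left TIR mutated to the configured pairwise identity before
#' reverse-complementing, so the planted pair identity matches
#' \code{cfg$tir_identity} up to sampling noise.
#'
#' @param cfg a [sim_config()].
#' @param defect_labels character subset of
#'   \code{dde_mut, start_mut, frameshift, premature_stop, deletion}
#'   (empty = intact).
#' @param ref reference transposase from [make_reference_transposase()];
#'   generated from \code{cfg$seed} when missing.
#' @return list with \code{seq} (element, TSD excluded), \code{tsd},
#'   \code{truth} (TIR/CDS spans in element coordinates, planted defects,
#'   insertion list).
#' @export
plant_mule <- function(cfg, defect_labels = character(), ref = NULL) {
  stopifnot(all(defect_labels %in% setdiff(DEFECT_KINDS, "intact")))
  if (is.null(ref)) ref <- make_reference_transposase(cfg$seed)
  tir_len <- sample(cfg$tir_len_range[1]:cfg$tir_len_range[2], 1)
  tirL <- random_dna(tir_len, 0.5)
  n_mut <- round((1 - cfg$tir_identity) * tir_len)
  tirR_core <- mutate_sites(tirL, n_mut)
  pad5 <- random_dna(sample(100:400, 1), cfg$gc)
  pad3 <- random_dna(sample(100:400, 1), cfg$gc)
  cds <- back_translate(ref$protein)
  details <- list()
  avoid <- integer()
  # point defects first, then deletion, then frameshift (stable coordinates)
  for (lab in intersect(c("dde_mut", "start_mut", "premature_stop", "deletion",
                          "frameshift"), defect_labels)) {
    r <- apply_defect(cds, lab, ref, avoid = avoid)
    cds <- r$cds
    if (!is.null(r$detail$aa_pos)) avoid <- c(avoid, r$detail$aa_pos)
    details[[lab]] <- r$detail
  }
  seq <- paste0(tirL, pad5, cds, pad3, revcomp(tirR_core))
  if (nchar(seq) < 2000 || nchar(seq) > 30000) stop("planted element outside 2-30 kb")
  tsd_len <- sample(cfg$tsd_len_range[1]:cfg$tsd_len_range[2], 1)
  cds_start <- tir_len + nchar(pad5) + 1L
  list(seq = seq,
       tsd = random_dna(tsd_len, cfg$gc),
       truth = list(
         tir_len = tir_len,
         tir_identity = 1 - n_mut / tir_len,
         tirL = c(1L, tir_len),
         tirR = c(nchar(seq) - tir_len + 1L, nchar(seq)),
         cds = c(cds_start, cds_start + nchar(cds) - 1L),
         defects = defect_labels,
         defect_detail = details,
         insertions = list()))
}

#' Insert a nested transposable element into a planted MULE
#'
#' The nested TE lands at a uniform position between the host TIRs and
#' duplicates a short target site, as real insertions do. For an LTR
#' retroelement the two LTRs are mutated independently so their expected
#' divergence is \eqn{d = 2 r T} with \eqn{r = 1.3\times10^{-8}}/site/yr.
#' Insertions that would push the host over 30 kb are rejected (host
#' returned unchanged, with a message).
#'
#' @param element list from [plant_mule()].
#' @param te_kind one of \code{"LTR_retro"}, \code{"MITE"}, \code{"DNA_TE"}.
#' @param target_age_myr insertion age for \code{LTR_retro}.
#' @return the modified element list; the new insertion record is appended
#'   to \code{element$truth$insertions}.
#' @export
insert_nested_te <- function(element, te_kind = c("LTR_retro", "MITE", "DNA_TE"),
                             target_age_myr = NULL) {
  te_kind <- match.arg(te_kind)
  tr <- element$truth
  if (te_kind == "LTR_retro") {
    if (is.null(target_age_myr)) stop("LTR_retro needs a target age")
    ltr_len <- sample(150:400, 1)
    ltr <- random_dna(ltr_len, 0.5)
    d_half <- LTR_SUBSTITUTION_RATE * target_age_myr * 1e6  # per-copy expected change
    ltr5 <- mutate_sites(ltr, stats::rbinom(1, ltr_len, d_half))
    ltr3 <- mutate_sites(ltr, stats::rbinom(1, ltr_len, d_half))
    te_seq <- paste0(ltr5, random_dna(sample(800:2500, 1), 0.5), ltr3)
    tsd_len <- 5L; family <- "Copia_synth"; te_class <- "RNA"
  } else if (te_kind == "MITE") {
    te_seq <- random_dna(274, 0.5)
    tsd_len <- 3L; family <- "Os0548_synth"; te_class <- "DNA"
    ltr5 <- ltr3 <- NULL
  } else {
    te_seq <- random_dna(sample(300:1000, 1), 0.5)
    tsd_len <- 8L; family <- "DNA_synth"; te_class <- "DNA"
    ltr5 <- ltr3 <- NULL
  }
  te_len <- nchar(te_seq)
  added <- te_len + tsd_len
  if (nchar(element$seq) + added > 30000) {
    message("nested insertion rejected: host would exceed 30 kb")
    return(element)
  }
  # uniform insertion point strictly between the TIRs, leaving room for the TSD
  p <- sample((tr$tirL[2] + 1L):(tr$tirR[1] - tsd_len), 1)
  host <- element$seq
  site <- substr(host, p, p + tsd_len - 1L)
  element$seq <- paste0(substr(host, 1, p + tsd_len - 1L), te_seq,
                        substr(host, p, nchar(host)))
  shift <- function(span) {
    if (span[1] >= p + tsd_len) span + added
    else if (span[2] >= p + tsd_len) c(span[1], span[2] + added)
    else span
  }
  in_coding <- p >= tr$cds[1] && p <= tr$cds[2]
  tr$tirL <- shift(tr$tirL); tr$tirR <- shift(tr$tirR); tr$cds <- shift(tr$cds)
  tr$insertions <- lapply(tr$insertions, function(ins) {
    ins$interval <- shift(ins$interval); ins$excise <- shift(ins$excise); ins
  })
  tr$insertions <- c(tr$insertions, list(list(
    te_kind = te_kind, family = family, te_class = te_class,
    length = te_len,
    interval = c(p + tsd_len, p + tsd_len + te_len - 1L),
    excise = c(p + tsd_len, p + tsd_len + te_len + tsd_len - 1L),
    tsd = site, in_coding = in_coding,
    ltr_age = if (te_kind == "LTR_retro") target_age_myr else NA_real_,
    ltr5 = ltr5, ltr3 = ltr3)))
  element$truth <- tr
  element
}

#' Simulate a genome with planted MULEs and ground truth
#'
#' Background sequence is i.i.d. at the configured GC; elements are placed
#' non-overlapping with their TSD copies flanking them. The annotation
#' table covers both the planted MULEs and their nested TEs so that
#' discovery and nesting can be validated independently. Same seed, same
#' output, byte for byte.
#'
#' @param cfg a [sim_config()].
#' @return list with \code{genome} (named character of length 1),
#'   \code{annotations} (TE table as in [parse_te_annotations()]),
#'   \code{truth} (per-element ground truth, genome coordinates),
#'   \code{ref} (the reference transposase used).
#' @export
simulate_genome <- function(cfg) {
  ref <- make_reference_transposase(cfg$seed)
  with_seed(cfg$seed + 1L, {
    elements <- vector("list", cfg$n_elements)
    labels <- if (cfg$n_elements > 0)
      sample(names(cfg$defect_spectrum), cfg$n_elements, replace = TRUE,
             prob = cfg$defect_spectrum) else character()
    for (i in seq_len(cfg$n_elements)) {
      el <- plant_mule(cfg, setdiff(labels[i], "intact"), ref = ref)
      k <- stats::rpois(1, cfg$nested_rate)
      for (j in seq_len(k)) {
        if (stats::runif(1) < cfg$nested_class_mix) {
          el <- insert_nested_te(el, "LTR_retro",
                                 target_age_myr = stats::runif(1, cfg$ltr_age_range[1],
                                                               cfg$ltr_age_range[2]))
        } else {
          el <- insert_nested_te(el, sample(c("MITE", "DNA_TE"), 1))
        }
      }
      elements[[i]] <- el
    }
    footprint <- sum(vapply(elements, function(e) nchar(e$seq) + 2L * nchar(e$tsd), 0L))
    min_gap <- 1000L
    slack <- cfg$genome_len - footprint - (cfg$n_elements + 1L) * min_gap
    if (slack < 0) stop("genome too small for n_elements")
    cuts <- sort(stats::runif(cfg$n_elements))
    gaps <- min_gap + round(diff(c(0, cuts, 1)) * slack)
    pieces <- character(0)
    truth <- list()
    ann <- list()
    pos <- 0L
    for (i in seq_len(cfg$n_elements)) {
      bg <- random_dna(gaps[i], cfg$gc)
      el <- elements[[i]]
      tsd <- el$tsd
      pieces <- c(pieces, bg, tsd, el$seq, tsd)
      pos <- pos + gaps[i] + nchar(tsd)
      s <- pos + 1L                      # element start (TSD excluded)
      e <- pos + nchar(el$seq)
      id <- sprintf("CM_sim%03d", i)
      tr <- el$truth
      truth[[id]] <- list(
        span = c(s, e), tsd = tsd,
        tirL = tr$tirL + s - 1L, tirR = tr$tirR + s - 1L,
        cds = tr$cds + s - 1L,
        defects = tr$defects, defect_detail = tr$defect_detail,
        insertions = lapply(tr$insertions, function(ins) {
          ins$genome_interval <- ins$interval + s - 1L
          ins
        }),
        element_seq = el$seq)
      ann[[length(ann) + 1L]] <- data.frame(
        seq_id = "synth_chr1", start = s, end = e, family = "MULE_synth",
        te_class = "DNA", strand = "+", stringsAsFactors = FALSE)
      for (ins in truth[[id]]$insertions) {
        ann[[length(ann) + 1L]] <- data.frame(
          seq_id = "synth_chr1", start = ins$genome_interval[1],
          end = ins$genome_interval[2], family = ins$family,
          te_class = ins$te_class, strand = "+", stringsAsFactors = FALSE)
      }
      pos <- pos + nchar(el$seq) + nchar(tsd)
    }
    pieces <- c(pieces, random_dna(gaps[cfg$n_elements + 1L], cfg$gc))
    genome <- chars_seq(pieces)
    annotations <- if (length(ann)) do.call(rbind, ann) else
      data.frame(seq_id = character(), start = integer(), end = integer(),
                 family = character(), te_class = character(),
                 strand = character(), stringsAsFactors = FALSE)
    list(genome = c(synth_chr1 = genome), annotations = annotations,
         truth = truth, ref = ref)
  })
}

#' Derive a diverged homolog of a sequence
#'
#' Substitutions are Binomial(L, sub_rate); indel events are
#' Poisson(L/1000 * indel_rate) with Geometric(p) lengths (support >= 1),
#' each an insertion or a deletion with equal probability. Realized event
#' counts are returned as ground truth.
#'
#' @param seq nucleotide string.
#' @param sub_rate substitutions per site.
#' @param indel_rate indel events per kb.
#' @param indel_len_geom_p geometric length parameter.
#' @return list with \code{seq} (the diverged copy) and \code{truth}
#'   (\code{n_sub, n_indels, indel_len_total}).
#' @export
mutate_homolog <- function(seq, sub_rate, indel_rate, indel_len_geom_p = 0.3) {
  L <- nchar(seq)
  n_sub <- stats::rbinom(1, L, sub_rate)
  out <- mutate_sites(seq, n_sub)
  n_indel <- stats::rpois(1, L / 1000 * indel_rate)
  lens <- if (n_indel > 0) stats::rgeom(n_indel, indel_len_geom_p) + 1L else integer()
  for (l in lens) {
    cur <- nchar(out)
    if (stats::runif(1) < 0.5 && cur > l + 2) {   # deletion
      p <- sample.int(cur - l, 1)
      out <- paste0(substr(out, 1, p - 1), substr(out, p + l, cur))
    } else {                                       # insertion
      p <- sample.int(cur, 1)
      out <- paste0(substr(out, 1, p), random_dna(l, 0.5), substr(out, p + 1, cur))
    }
  }
  list(seq = out,
       truth = list(n_sub = n_sub, n_indels = n_indel,
                    indel_len_total = sum(lens)))
}

#' Simulate EST records from a set of elements
#'
#' Each EST is a 300-1500 bp substring of a chosen element, mutated at up to
#' \code{mut_max} per site (default 0, i.e. exact substrings).
#'
#' @param elements named character vector of element sequences.
#' @param n number of ESTs.
#' @param mut_max maximum per-site mutation fraction (uniform in
#'   \code{[0, mut_max]} per EST).
#' @param len_range EST length range in bp.
#' @return list with \code{ests} (named character vector) and \code{truth}
#'   (data.frame \code{est_id, element_id, start, len, n_mut}).
#' @export
simulate_est_records <- function(elements, n, mut_max = 0,
                                 len_range = c(300L, 1500L)) {
  stopifnot(n >= 0, length(elements) > 0)
  ests <- character(n)
  truth <- vector("list", n)
  for (i in seq_len(n)) {
    ei <- sample(length(elements), 1)
    L <- nchar(elements[[ei]])
    len <- sample(len_range[1]:min(len_range[2], L), 1)
    s <- sample.int(L - len + 1L, 1)
    frag <- substr(elements[[ei]], s, s + len - 1L)
    n_mut <- if (mut_max > 0) stats::rbinom(1, len, stats::runif(1, 0, mut_max)) else 0L
    ests[i] <- mutate_sites(frag, n_mut)
    truth[[i]] <- data.frame(est_id = sprintf("EST%04d", i),
                             element_id = names(elements)[ei],
                             start = s, len = len, n_mut = n_mut,
                             stringsAsFactors = FALSE)
  }
  names(ests) <- sprintf("EST%04d", seq_len(n))
  list(ests = ests,
       truth = if (n > 0) do.call(rbind, truth) else
         data.frame(est_id = character(), element_id = character(),
                    start = integer(), len = integer(), n_mut = integer()))
}
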