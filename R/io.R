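#' Read genomic sequences from a FASTA file
#'
#' Sequences are uppercased, RNA \code{U} is converted to \code{T}, and any
#' residual character outside \code{A/C/G/T/N} is replaced by \code{N} (the
#' number of replacements is reported with a message). Internal coordinates
#' throughout the package are 1-based closed intervals, the
#' IRanges/Bioconductor convention; file formats state their own convention.
#'
#' @param path path to a FASTA file.
#' @return a named character vector, one element per record.
#' @export
parse_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0) stop("empty FASTA file: ", path)
  ids <- sub("\\s.*$", "", names(set))
  if (any(ids == "")) stop("FASTA record with empty id in ", path)
  if (anyDuplicated(ids)) stop("duplicate FASTA ids: ",
                               paste(unique(ids[duplicated(ids)]), collapse = ", "))
  seqs <- toupper(as.character(set))
  seqs <- chartr("U", "T", seqs)
  bad <- vapply(seqs, function(s) sum(seq_chars(s) %in% c("A","C","G","T","N") == FALSE), 0L)
  if (sum(bad) > 0) {
    message(sum(bad), " non-ACGTN characters replaced by N")
    seqs <- vapply(seqs, function(s) gsub("[^ACGTN]", "N", s), "")
  }
  if (any(nchar(seqs) == 0)) stop("zero-length sequence in ", path)
  stats::setNames(unname(seqs), ids)
}

#' Read protein sequences from a FASTA file
#'
#' @param path path to a protein FASTA file.
#' @return a named character vector of amino-acid sequences (uppercased).
#' @export
parse_protein_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0) stop("empty FASTA file: ", path)
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids)) stop("duplicate FASTA ids in ", path)
  stats::setNames(toupper(as.character(set)), ids)
}

#' Write sequences to FASTA
#'
#' @param seqs named character vector.
#' @param path output path.
#' @export
write_fasta <- function(seqs, path) {
  set <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

# Infer RNA/DNA class from a RepeatMasker-style class/family string.
infer_te_class <- function(cls) {
  rna <- grepl("LTR|LINE|SINE|Copia|Gypsy|Retro", cls, ignore.case = TRUE)
  dna <- grepl("DNA|MITE|Helitron|TIR|Tourist|Stowaway|Mutator|MULE|hAT|CACTA|PIF", cls, ignore.case = TRUE)
  ifelse(rna, "RNA", ifelse(dna, "DNA", NA_character_))
}

#' Read a transposable-element annotation table
#'
#' Accepts either a 5/6-column TSV (\code{seq_id, start, end, family,
#' strand[, te_class]}) or a RepeatMasker \code{.out}-style whitespace table.
#' Coordinates in both dialects are 1-based inclusive and are kept as such.
#'
#' @param path input path.
#' @param class_table optional named character vector mapping family to
#'   \code{"RNA"} or \code{"DNA"}.
#' @param default_class optional fallback class for unknown families; when
#'   \code{NULL} (default) an unknown, uninferable family is an error.
#' @return data.frame with columns \code{seq_id, start, end, family,
#'   te_class, strand}.
#' @export
parse_te_annotations <- function(path, class_table = NULL, default_class = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  is_rm <- length(lines) > 0 && grepl("^\\s*(SW|score)\\b", lines[1])
  if (is_rm) {
    body <- lines[!grepl("^\\s*(SW|score|$)", lines)]
    body <- body[grepl("^\\s*[0-9]", body)]
    f <- strsplit(trimws(body), "\\s+")
    df <- data.frame(
      seq_id = vapply(f, `[`, "", 5),
      start  = as.integer(vapply(f, `[`, "", 6)),
      end    = as.integer(vapply(f, `[`, "", 7)),
      strand = ifelse(vapply(f, `[`, "", 9) == "C", "-", "+"),
      family = vapply(f, `[`, "", 10),
      clsfam = vapply(f, `[`, "", 11),
      stringsAsFactors = FALSE)
  } else {
    df <- utils::read.table(path, sep = "\t", header = FALSE, stringsAsFactors = FALSE)
    if (ncol(df) < 5) stop("TE annotation TSV needs >= 5 columns")
    names(df)[1:5] <- c("seq_id", "start", "end", "family", "strand")
    df$clsfam <- if (ncol(df) >= 6) as.character(df[[6]]) else NA_character_
    df <- df[, c("seq_id", "start", "end", "strand", "family", "clsfam")]
  }
  if (any(df$start > df$end)) stop("TE annotation with start > end")
  cls <- rep(NA_character_, nrow(df))
  if (!is.null(class_table)) cls <- unname(class_table[df$family])
  idx <- is.na(cls) & !is.na(df$clsfam) & df$clsfam %in% c("RNA", "DNA")
  cls[idx] <- df$clsfam[idx]
  idx <- is.na(cls)
  cls[idx] <- infer_te_class(ifelse(is.na(df$clsfam[idx]), df$family[idx], df$clsfam[idx]))
  if (anyNA(cls)) {
    if (is.null(default_class))
      stop("unknown TE family with no class mapping: ",
           paste(unique(df$family[is.na(cls)]), collapse = ", "))
    warning("unknown families assigned class ", default_class)
    cls[is.na(cls)] <- default_class
  }
  data.frame(seq_id = df$seq_id, start = as.integer(df$start), end = as.integer(df$end),
             family = df$family, te_class = cls, strand = df$strand,
             stringsAsFactors = FALSE)
}

#' Write a TE annotation table (6-column TSV, 1-based inclusive)
#'
#' @param ann data.frame as returned by [parse_te_annotations()].
#' @param path output path.
#' @export
write_te_annotations <- function(ann, path) {
  utils::write.table(ann[, c("seq_id", "start", "end", "family", "strand", "te_class")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write element calls to GFF3
#'
#' Emits \code{mule_element}, \code{terminal_inverted_repeat},
#' \code{target_site_duplication}, \code{nested_insertion} and
#' \code{coding_region} features with stable \code{ID} attributes. GFF3
#' coordinates are 1-based inclusive, identical to the internal convention.
#'
#' @param features data.frame with columns \code{seqid, type, start, end,
#'   strand, id} and optionally \code{parent, score}.
#' @param path output path.
#' @export
write_gff3 <- function(features, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  if (is.null(features) || nrow(features) == 0) return(invisible(path))
  score <- if ("score" %in% names(features)) features$score else rep(NA, nrow(features))
  parent <- if ("parent" %in% names(features)) features$parent else rep(NA, nrow(features))
  attrs <- paste0("ID=", features$id,
                  ifelse(is.na(parent) | parent == "", "", paste0(";Parent=", parent)))
  lines <- paste(features$seqid, "mulescan", features$type,
                 features$start, features$end,
                 ifelse(is.na(score), ".", format(score, trim = TRUE)),
                 features$strand, ".", attrs, sep = "\t")
  writeLines(lines, con)
  invisible(path)
}

#' Read a GFF3 file written by [write_gff3()]
#'
#' @param path GFF3 path.
#' @return data.frame with columns \code{seqid, type, start, end, strand, id,
#'   parent}.
#' @export
read_gff3 <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  if (length(lines) == 0)
    return(data.frame(seqid = character(), type = character(), start = integer(),
                      end = integer(), strand = character(), id = character(),
                      parent = character(), stringsAsFactors = FALSE))
  f <- strsplit(lines, "\t", fixed = TRUE)
  attr_get <- function(a, key) {
    m <- regmatches(a, regexec(paste0("(^|;)", key, "=([^;]*)"), a))[[1]]
    if (length(m) >= 3) m[3] else NA_character_
  }
  a <- vapply(f, `[`, "", 9)
  data.frame(
    seqid = vapply(f, `[`, "", 1),
    type = vapply(f, `[`, "", 3),
    start = as.integer(vapply(f, `[`, "", 4)),
    end = as.integer(vapply(f, `[`, "", 5)),
    strand = vapply(f, `[`, "", 7),
    id = vapply(a, attr_get, "", key = "ID"),
    parent = vapply(a, attr_get, "", key = "Parent"),
    stringsAsFactors = FALSE)
}

#' Convert candidate element calls to a GFF3 feature table
#'
#' @param candidates data.frame of calls from [call_candidate_elements()].
#' @return data.frame suitable for [write_gff3()].
#' @export
elements_to_gff <- function(candidates) {
  if (nrow(candidates) == 0)
    return(data.frame(seqid = character(), type = character(), start = integer(),
                      end = integer(), strand = character(), id = character()))
  el <- data.frame(seqid = candidates$seq_id, type = "mule_element",
                   start = candidates$start, end = candidates$end,
                   strand = candidates$strand, id = candidates$id,
                   parent = NA_character_, stringsAsFactors = FALSE)
  tirs <- rbind(
    data.frame(seqid = candidates$seq_id, type = "terminal_inverted_repeat",
               start = candidates$tir_left_start, end = candidates$tir_left_end,
               strand = candidates$strand, id = paste0(candidates$id, "_tirL"),
               parent = candidates$id, stringsAsFactors = FALSE),
    data.frame(seqid = candidates$seq_id, type = "terminal_inverted_repeat",
               start = candidates$tir_right_start, end = candidates$tir_right_end,
               strand = candidates$strand, id = paste0(candidates$id, "_tirR"),
               parent = candidates$id, stringsAsFactors = FALSE))
  tsds <- rbind(
    data.frame(seqid = candidates$seq_id, type = "target_site_duplication",
               start = candidates$start - candidates$tsd_len, end = candidates$start - 1L,
               strand = candidates$strand, id = paste0(candidates$id, "_tsdL"),
               parent = candidates$id, stringsAsFactors = FALSE),
    data.frame(seqid = candidates$seq_id, type = "target_site_duplication",
               start = candidates$end + 1L, end = candidates$end + candidates$tsd_len,
               strand = candidates$strand, id = paste0(candidates$id, "_tsdR"),
               parent = candidates$id, stringsAsFactors = FALSE))
  rbind(el, tirs, tsds)
}
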