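# Mutation-context channel classifiers: SBS-96, DBS-78 and ID-83 following
# the COSMIC conventions (pyrimidine-strand canonical SBS labels,
# reverse-complement-collapsed doublets, indels binned by homopolymer/repeat
# length with repeat-before-microhomology tie-breaking).

BASES <- c("A", "C", "G", "T")
COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

revcomp <- function(x) {
  chartr("ACGT", "TGCA", sapply(strsplit(x, NULL), function(b)
    paste(rev(b), collapse = "")))
}

SBS_SUBS <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")

#' SBS-96 channel labels in canonical order
#'
#' @return character vector of the 96 trinucleotide substitution channels,
#'   substitution-major (`C>A` block first), then 5' and 3' base.
#' @export
sbs96_channels <- function() {
  unlist(lapply(SBS_SUBS, function(s) {
    as.vector(t(outer(BASES, BASES, function(f, t)
      paste0(f, "[", s, "]", t))))
  }))
}

#' Classify a single-base substitution into its SBS-96 channel
#'
#' Labels follow the pyrimidine-strand convention: substitutions with a
#' purine reference base are reverse-complemented (including flanks) so the
#' central reference base is always C or T.
#'
#' @param ref,alt single reference/alternate bases, `ref != alt`.
#' @param context5,context3 flanking reference bases (at least one each
#'   side; only the base adjacent to the variant is used). Vectorised.
#' @return channel label(s) of the form `"A[C>A]A"`.
#' @export
classify_sbs96 <- function(ref, alt, context5, context3) {
  n <- length(ref)
  stopifnot(length(alt) == n, length(context5) == n, length(context3) == n)
  ref <- toupper(ref); alt <- toupper(alt)
  f5 <- toupper(substr(context5, nchar(context5), nchar(context5)))
  f3 <- toupper(substr(context3, 1L, 1L))
  ok <- ref %in% BASES & alt %in% BASES & f5 %in% BASES & f3 %in% BASES
  if (!all(ok)) stop("non-ACGT base in SBS context at record(s): ",
                     paste(utils::head(which(!ok), 5), collapse = ", "))
  if (any(ref == alt)) stop("ref == alt is not a substitution")
  flip <- ref %in% c("A", "G")
  r <- ifelse(flip, COMPLEMENT[ref], ref)
  a <- ifelse(flip, COMPLEMENT[alt], alt)
  l <- ifelse(flip, COMPLEMENT[f3], f5)
  rgt <- ifelse(flip, COMPLEMENT[f5], f3)
  paste0(l, "[", r, ">", a, "]", rgt)
}

# Official COSMIC DBS-78 canonical channel table.
DBS78_TABLE <- c(
  "AC>CA","AC>CG","AC>CT","AC>GA","AC>GG","AC>GT","AC>TA","AC>TG","AC>TT",
  "AT>CA","AT>CC","AT>CG","AT>GA","AT>GC","AT>TA",
  "CC>AA","CC>AG","CC>AT","CC>GA","CC>GG","CC>GT","CC>TA","CC>TG","CC>TT",
  "CG>AT","CG>GC","CG>GT","CG>TA","CG>TC","CG>TT",
  "CT>AA","CT>AC","CT>AG","CT>GA","CT>GC","CT>GG","CT>TA","CT>TC","CT>TG",
  "GC>AA","GC>AG","GC>AT","GC>CA","GC>CG","GC>TA",
  "TA>AT","TA>CG","TA>CT","TA>GC","TA>GG","TA>GT",
  "TC>AA","TC>AG","TC>AT","TC>CA","TC>CG","TC>CT","TC>GA","TC>GG","TC>GT",
  "TG>AA","TG>AC","TG>AT","TG>CA","TG>CC","TG>CT","TG>GA","TG>GC","TG>GT",
  "TT>AA","TT>AC","TT>AG","TT>CA","TT>CC","TT>CG","TT>GA","TT>GC","TT>GG"
)

#' DBS-78 channel labels in canonical order
#' @return character vector of the 78 doublet substitution channels.
#' @export
dbs78_channels <- function() DBS78_TABLE

#' Classify a doublet-base substitution into its DBS-78 channel
#'
#' Reverse-complement pairs are collapsed onto the canonical COSMIC
#' representative. Both positions of the doublet must change; a doublet
#' changing at only one position is a single-base substitution and is
#' rejected.
#'
#' @param ref_dinuc,alt_dinuc two-base reference/alternate strings
#'   (vectorised).
#' @return channel label(s) such as `"CC>AA"`.
#' @export
classify_dbs78 <- function(ref_dinuc, alt_dinuc) {
  ref_dinuc <- toupper(ref_dinuc); alt_dinuc <- toupper(alt_dinuc)
  if (any(nchar(ref_dinuc) != 2L | nchar(alt_dinuc) != 2L)) {
    stop("DBS requires two-base ref and alt")
  }
  if (any(!grepl("^[ACGT]{2}$", ref_dinuc) | !grepl("^[ACGT]{2}$", alt_dinuc))) {
    stop("non-ACGT base in DBS")
  }
  same1 <- substr(ref_dinuc, 1, 1) == substr(alt_dinuc, 1, 1)
  same2 <- substr(ref_dinuc, 2, 2) == substr(alt_dinuc, 2, 2)
  if (any(same1 | same2)) {
    stop("doublet changing at fewer than two positions is not a DBS")
  }
  lab <- paste0(ref_dinuc, ">", alt_dinuc)
  need_rc <- !(lab %in% DBS78_TABLE)
  if (any(need_rc)) {
    lab[need_rc] <- paste0(revcomp(ref_dinuc[need_rc]), ">",
                           revcomp(alt_dinuc[need_rc]))
  }
  bad <- !(lab %in% DBS78_TABLE)
  if (any(bad)) stop("unclassifiable DBS: ", paste(lab[bad], collapse = ", "))
  lab
}

#' ID-83 channel labels in canonical order
#'
#' Channels follow the COSMIC/SigProfiler scheme and index convention:
#' for deletions the trailing number is (homopolymer or repeat-unit count
#' minus one) capped at 5, for insertions it is the count of pre-existing
#' adjacent copies capped at 5, and `M` channels carry the microhomology
#' length.
#'
#' @return character vector of the 83 indel channels.
#' @export
id83_channels <- function() {
  c(paste0("1:Del:C:", 0:5), paste0("1:Del:T:", 0:5),
    paste0("1:Ins:C:", 0:5), paste0("1:Ins:T:", 0:5),
    paste0("2:Del:R:", 0:5), paste0("3:Del:R:", 0:5),
    paste0("4:Del:R:", 0:5), paste0("5:Del:R:", 0:5),
    paste0("2:Ins:R:", 0:5), paste0("3:Ins:R:", 0:5),
    paste0("4:Ins:R:", 0:5), paste0("5:Ins:R:", 0:5),
    "2:Del:M:1", paste0("3:Del:M:", 1:2), paste0("4:Del:M:", 1:3),
    paste0("5:Del:M:", 1:5))
}

# run length of `base` at the end of s (reading backwards)
run_at_tail <- function(s, base) {
  n <- nchar(s); i <- 0L
  while (i < n && substr(s, n - i, n - i) == base) i <- i + 1L
  i
}
# run length of `base` at the start of s
run_at_head <- function(s, base) {
  n <- nchar(s); i <- 0L
  while (i < n && substr(s, i + 1L, i + 1L) == base) i <- i + 1L
  i
}
# number of tandem copies of `unit` at the start of s
copies_at_head <- function(s, unit) {
  k <- nchar(unit); i <- 0L
  while (nchar(s) >= (i + 1L) * k &&
         substr(s, i * k + 1L, (i + 1L) * k) == unit) i <- i + 1L
  i
}
# number of tandem copies of `unit` at the end of s
copies_at_tail <- function(s, unit) {
  k <- nchar(unit); n <- nchar(s); i <- 0L
  while (n >= (i + 1L) * k &&
         substr(s, n - (i + 1L) * k + 1L, n - i * k) == unit) i <- i + 1L
  i
}
# longest m < len such that a prefix of seq continues into context3 or a
# suffix of seq is echoed at the end of context5 (partial-copy homology)
microhomology_len <- function(seq, context5, context3) {
  len <- nchar(seq); best <- 0L
  for (m in seq_len(len - 1L)) {
    pre <- substr(seq, 1L, m)
    suf <- substr(seq, len - m + 1L, len)
    if (nchar(context3) >= m && substr(context3, 1L, m) == pre) best <- max(best, m)
    if (nchar(context5) >= m &&
        substr(context5, nchar(context5) - m + 1L, nchar(context5)) == suf) {
      best <- max(best, m)
    }
  }
  best
}

#' Classify an insertion or deletion into its ID-83 channel
#'
#' Implements the COSMIC indel decision tree: 1-bp events are binned by the
#' pyrimidine-normalised base (A/G complemented to T/C) and the length of
#' the homopolymer they sit in; longer events by length and the number of
#' additional tandem copies of the inserted/deleted sequence in the
#' flanking reference; deletions with no extra copy but partial flanking
#' homology fall into the microhomology channels. A full extra repeat copy
#' takes precedence over microhomology.
#'
#' @param ref deleted sequence, or `"-"` for insertions (MAF convention).
#' @param alt inserted sequence, or `"-"` for deletions.
#' @param context5,context3 flanking reference sequence 5' and 3' of the
#'   event; enough flank must be supplied to resolve the repeat bins
#'   (the generator emits 10 bp each side).
#' @return a single channel label such as `"1:Del:T:4"` or `"3:Del:M:2"`.
#' @export
classify_id83 <- function(ref, alt, context5, context3) {
  ref <- toupper(ref); alt <- toupper(alt)
  if (is.na(context5) || is.na(context3) || context5 == "" || context3 == "") {
    stop("indel classification requires flanking context")
  }
  context5 <- toupper(context5); context3 <- toupper(context3)
  is_del <- alt %in% c("-", "") && grepl("^[ACGT]+$", ref)
  is_ins <- ref %in% c("-", "") && grepl("^[ACGT]+$", alt)
  if (!is_del && !is_ins) stop("not a simple insertion or deletion: ",
                               ref, ">", alt)
  seq <- if (is_del) ref else alt
  len <- nchar(seq)
  lenb <- min(len, 5L)
  if (len == 1L) {
    base <- if (seq %in% c("A", "G")) unname(COMPLEMENT[seq]) else seq
    homlen <- run_at_tail(context5, seq) + run_at_head(context3, seq)
    if (is_del) {
      # homopolymer includes the deleted base itself; index = length - 1
      return(paste0("1:Del:", base, ":", min(homlen, 5L)))
    }
    return(paste0("1:Ins:", base, ":", min(homlen, 5L)))
  }
  extra <- copies_at_head(context3, seq) + copies_at_tail(context5, seq)
  if (is_ins) return(paste0(lenb, ":Ins:R:", min(extra, 5L)))
  if (extra >= 1L) return(paste0(lenb, ":Del:R:", min(extra, 5L)))
  mh <- microhomology_len(seq, context5, context3)
  if (mh >= 1L) {
    mh_cap <- if (lenb == 5L) 5L else lenb - 1L
    return(paste0(lenb, ":Del:M:", min(mh, mh_cap)))
  }
  paste0(lenb, ":Del:R:0")
}

#' Build a mutation catalog matrix
#'
#' Counts each sample's classifiable mutations into SBS-96, DBS-78 or
#' ID-83 channels. Records of the requested kind that lack flanking
#' context (or fail classification) are skipped with a warning and counted
#' in the `skipped` field, so `classified + skipped` equals the number of
#' candidate mutations of that kind.
#'
#' @param cohort a `mutscape_cohort` (or a mutation `data.table`).
#' @param kind one of `"SBS96"`, `"DBS78"`, `"ID83"`.
#' @param samples optional sample ids fixing the row set and order;
#'   defaults to all mutated samples.
#' @return object of class `mutscape_catalog`: list with `counts`
#'   (samples x channels integer matrix), `kind`, `skipped`.
#' @export
build_catalog <- function(cohort, kind = c("SBS96", "DBS78", "ID83"),
                          samples = NULL) {
  kind <- match.arg(kind)
  mut <- if (inherits(cohort, "mutscape_cohort")) cohort$mutations else cohort
  if (is.null(samples)) samples <- sort(unique(mut$sample_id))
  channels <- switch(kind, SBS96 = sbs96_channels(),
                     DBS78 = dbs78_channels(), ID83 = id83_channels())
  sub <- switch(kind,
    SBS96 = mut[mut$variant_type == "SNP", ],
    DBS78 = mut[mut$variant_type == "DNP", ],
    ID83  = mut[mut$variant_type %in% c("INS", "DEL"), ])
  counts <- matrix(0L, length(samples), length(channels),
                   dimnames = list(samples, channels))
  skipped <- 0L
  if (nrow(sub) > 0L) {
    labels <- rep(NA_character_, nrow(sub))
    if (kind == "SBS96") {
      has_ctx <- !is.na(sub$context5) & !is.na(sub$context3) &
        nchar(sub$context5) >= 1L & nchar(sub$context3) >= 1L
      if (any(has_ctx)) {
        labels[has_ctx] <- classify_sbs96(sub$ref_allele[has_ctx],
                                          sub$alt_allele[has_ctx],
                                          sub$context5[has_ctx],
                                          sub$context3[has_ctx])
      }
    } else if (kind == "DBS78") {
      for (i in seq_len(nrow(sub))) {
        labels[i] <- tryCatch(
          classify_dbs78(sub$ref_allele[i], sub$alt_allele[i]),
          error = function(e) NA_character_)
      }
    } else {
      for (i in seq_len(nrow(sub))) {
        labels[i] <- tryCatch(
          classify_id83(sub$ref_allele[i], sub$alt_allele[i],
                        sub$context5[i], sub$context3[i]),
          error = function(e) NA_character_)
      }
    }
    keep <- !is.na(labels) & sub$sample_id %in% samples
    skipped <- sum(!keep)
    if (skipped > 0L) {
      warning(skipped, " ", kind,
              " candidate record(s) skipped (missing/invalid context)")
    }
    if (any(keep)) {
      tab <- table(factor(sub$sample_id[keep], levels = samples),
                   factor(labels[keep], levels = channels))
      counts <- matrix(as.integer(tab), nrow = length(samples),
                       dimnames = list(samples, channels))
    }
  }
  structure(list(counts = counts, kind = kind, skipped = skipped),
            class = "mutscape_catalog")
}

#' @export
print.mutscape_catalog <- function(x, ...) {
  cat("mutscape catalog [", x$kind, "]: ", nrow(x$counts), " samples x ",
      ncol(x$counts), " channels, ", sum(x$counts), " mutations (",
      x$skipped, " skipped)\n", sep = "")
  invisible(x)
}

#' Write a catalog as a channels-by-samples TSV
#'
#' Channels are emitted as rows in canonical order (the layout reference
#' signature files use), samples as columns.
#' @param catalog a `mutscape_catalog`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_catalog <- function(catalog, path) {
  dt <- data.table::data.table(channel = colnames(catalog$counts))
  for (s in rownames(catalog$counts)) dt[[s]] <- catalog$counts[s, ]
  data.table::fwrite(dt, path, sep = "\t", quote = FALSE)
  invisible(path)
}
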