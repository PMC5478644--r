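# NNCN sequence-context pipeline: design four 104-nt oligos that tile all
# 64 NNCN motifs (20-nt flank + 16 x 4-nt motifs + 20-nt flank), align
# clone reads against the reference, call C->T transitions at every
# non-flank C position, and aggregate per-motif deamination frequencies.

ALL_NNCN_MOTIFS <- function() {
  nts <- c("A", "C", "G", "T")
  g <- expand.grid(n3 = nts, n2 = nts, n1 = nts, stringsAsFactors = FALSE)
  sort(paste0(g$n1, g$n2, "C", g$n3))
}

# Default 20-nt C-free flanks (primer binding sites). C-free so the flank
# regions can never contribute deamination events.
DEFAULT_FLANK5 <- "GATTGGAAGTAGGTGGATGA"
DEFAULT_FLANK3 <- "TAGTGGATGTTGAGGTTAGG"

#' Design the NNCN motif-tiling oligo set
#'
#' Partitions the 64 NNCN 4-mers (third base C, N any nucleotide) into
#' four disjoint lists of 16, shuffled deterministically by `seed`, and
#' tiles each list contiguously between two 20-nt C-free flanks:
#' each oligo is flank5 + 16 x 4 nt + flank3 = 104 nt. Because a motif's
#' N slots may themselves be C, tiling creates incidental C positions;
#' every C position on the analyzed strand is indexed with its actual
#' 4-mer context (intended and incidental).
#'
#' @param flank5,flank3 20-nt C-free primer-site flanks.
#' @param seed integer controlling the motif shuffle/partition.
#' @return object of class `NncnDesign`: `oligos` (4 named sequences),
#'   `motif_assignment` (list of 4 motif vectors), the flanks, and
#'   `c_index` — a data.frame of every analyzable C position (oligo,
#'   position, 4-mer context).
#' @export
design_nncn_oligos <- function(flank5 = DEFAULT_FLANK5,
                               flank3 = DEFAULT_FLANK3, seed = 1) {
  if (nchar(flank5) != 20L || nchar(flank3) != 20L) {
    stop("flanks must be exactly 20 nt")
  }
  if (grepl("C", flank5) || grepl("C", flank3)) {
    stop("design error: flanks must be C-free on the analyzed strand")
  }
  if (!grepl("^[AGT]+$", flank5) || !grepl("^[AGT]+$", flank3)) {
    stop("flanks must be over A/G/T")
  }
  motifs <- with_seed(seed, sample(ALL_NNCN_MOTIFS()))
  assignment <- split(motifs, rep(1:4, each = 16L))
  names(assignment) <- paste0("NNCN_", 1:4)
  oligos <- vapply(assignment, function(m) {
    paste0(flank5, paste(m, collapse = ""), flank3)
  }, character(1L))
  stopifnot(all(nchar(oligos) == 104L))
  c_index <- do.call(rbind, lapply(names(oligos), function(id) {
    seqn <- oligos[[id]]
    pos <- which(strsplit(seqn, "")[[1L]] == "C")
    pos <- pos[pos > 20L & pos <= 84L]  # exclude flanks
    ctx <- vapply(pos, function(p) substr(seqn, p - 2L, p + 1L), character(1L))
    if (!length(pos)) return(NULL)
    data.frame(oligo = id, position = pos, context = ctx,
               stringsAsFactors = FALSE)
  }))
  structure(list(oligos = oligos, motif_assignment = assignment,
                 flank5 = flank5, flank3 = flank3, c_index = c_index,
                 seed = seed),
            class = "NncnDesign")
}

#' Write / read an NNCN design as FASTA
#'
#' Oligos are written one record each; the header carries the design
#' seed so re-reads can verify provenance.
#'
#' @param design an `NncnDesign`.
#' @param path FASTA path.
#' @return `path` invisibly (write) / named character vector of
#'   sequences (read).
#' @export
write_design_fasta <- function(design, path) {
  lines <- unlist(lapply(names(design$oligos), function(id) {
    c(sprintf(">%s seed=%d", id, design$seed), design$oligos[[id]])
  }))
  writeLines(lines, path)
  invisible(path)
}

#' Read a FASTA file into a named character vector
#' @param path FASTA path.
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- grep("^>", lines)
  if (!length(hdr)) stop("no FASTA records in ", path)
  ids <- sub("^>", "", lines[hdr])
  ids <- vapply(strsplit(ids, "\\s+"), `[[`, character(1L), 1L)
  ends <- c(hdr[-1L] - 1L, length(lines))
  seqs <- vapply(seq_along(hdr), function(i) {
    paste(lines[(hdr[i] + 1L):ends[i]], collapse = "")
  }, character(1L))
  stats::setNames(toupper(gsub("\\s", "", seqs)), ids)
}

#' Write named sequences to FASTA
#' @param seqs named character vector.
#' @param path FASTA path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  lines <- unlist(lapply(names(seqs), function(id) c(paste0(">", id), seqs[[id]])))
  writeLines(lines, path)
  invisible(path)
}

#' Globally align a clone read against its reference
#'
#' Needleman-Wunsch global alignment with match +1, mismatch -1, gap -2
#' and a deterministic traceback tie-break (diagonal over up over left).
#' Columns are classified as identical, substitution or indel.
#'
#' @param reference,clone non-empty A/C/G/T/N strings.
#' @return object of class `CloneAlignment`: aligned `reference` and
#'   `clone` rows (with `-` gaps), the alignment `score`, per-column
#'   `classification`, and `ref_pos` mapping columns to ungapped
#'   reference coordinates (NA at reference gaps).
#' @export
align_clone <- function(reference, clone) {
  if (!nzchar(reference) || !nzchar(clone)) stop("empty sequence")
  r <- strsplit(toupper(reference), "")[[1L]]
  q <- strsplit(toupper(clone), "")[[1L]]
  n <- length(r)
  m <- length(q)
  gap <- -2
  score <- matrix(0, n + 1L, m + 1L)
  # 1 = diagonal, 2 = up (gap in clone), 3 = left (gap in reference)
  move <- matrix(0L, n + 1L, m + 1L)
  score[, 1L] <- gap * (0:n)
  score[1L, ] <- gap * (0:m)
  move[-1L, 1L] <- 2L
  move[1L, -1L] <- 3L
  for (i in seq_len(n)) {
    sub_i <- ifelse(q == r[i], 1, -1)
    for (j in seq_len(m)) {
      cand <- c(score[i, j] + sub_i[j], score[i, j + 1L] + gap,
                score[i + 1L, j] + gap)
      best <- which.max(cand)  # first maximum: diagonal > up > left
      score[i + 1L, j + 1L] <- cand[best]
      move[i + 1L, j + 1L] <- best
    }
  }
  # traceback
  ar <- character(0)
  aq <- character(0)
  i <- n + 1L
  j <- m + 1L
  while (i > 1L || j > 1L) {
    mv <- move[i, j]
    if (mv == 1L) {
      ar <- c(r[i - 1L], ar); aq <- c(q[j - 1L], aq); i <- i - 1L; j <- j - 1L
    } else if (mv == 2L) {
      ar <- c(r[i - 1L], ar); aq <- c("-", aq); i <- i - 1L
    } else {
      ar <- c("-", ar); aq <- c(q[j - 1L], aq); j <- j - 1L
    }
  }
  classification <- ifelse(ar == "-" | aq == "-", "indel",
                           ifelse(ar == aq, "identical", "substitution"))
  ref_pos <- rep(NA_integer_, length(ar))
  ref_pos[ar != "-"] <- seq_len(n)
  structure(list(reference = paste(ar, collapse = ""),
                 clone = paste(aq, collapse = ""),
                 score = score[n + 1L, m + 1L],
                 columns = data.frame(ref = ar, clone = aq,
                                      classification = classification,
                                      ref_pos = ref_pos,
                                      stringsAsFactors = FALSE)),
            class = "CloneAlignment")
}

#' Call per-site deamination events from a clone alignment
#'
#' For every C position of the designated oligo outside the 20-nt
#' flanks, reports one event: `unmutated`, `C->T` (the deamination
#' signature read as a C-to-T transition), `other_substitution`, or
#' `indel_adjacent` (position within one alignment column of an indel;
#' excluded from frequency denominators because the polymerase, not the
#' deaminase, is the presumed cause).
#'
#' @param aln a `CloneAlignment` whose reference row is the designated
#'   oligo.
#' @param design an `NncnDesign`.
#' @param oligo_id which design oligo the reference is (e.g.
#'   `"NNCN_1"`).
#' @return data.frame with `position` (reference coordinate), `context`
#'   (4-mer, C third), `event`.
#' @export
call_transitions <- function(aln, design, oligo_id) {
  stopifnot(inherits(aln, "CloneAlignment"), inherits(design, "NncnDesign"))
  refseq <- gsub("-", "", aln$reference)
  if (!identical(refseq, unname(design$oligos[[oligo_id]]))) {
    stop("input error: alignment reference does not match design oligo ",
         oligo_id)
  }
  sites <- design$c_index[design$c_index$oligo == oligo_id, , drop = FALSE]
  cols <- aln$columns
  indel_cols <- which(cols$classification == "indel")
  events <- vapply(seq_len(nrow(sites)), function(i) {
    p <- sites$position[i]
    col <- which(cols$ref_pos == p)
    near_indel <- length(indel_cols) &&
      any(abs(indel_cols - col) <= 1L)
    if (near_indel) return("indel_adjacent")
    base <- cols$clone[col]
    if (base == "C") "unmutated"
    else if (base == "T") "C->T"
    else "other_substitution"
  }, character(1L))
  data.frame(position = sites$position, context = sites$context,
             event = events, stringsAsFactors = FALSE)
}

#' Aggregate called events into a per-motif frequency table
#'
#' Pools events over all clones and oligos and reports, per NNCN motif,
#' the number of eligible C sites observed (site x clone observations,
#' indel-adjacent calls excluded), the C->T transition count and the
#' per-site frequency. Motifs with zero eligible observations are
#' flagged `absent`. The summary flag `no_detectable_activity` is set
#' when the total C->T count is zero across at least `min_clones`
#' clones.
#'
#' @param events list of per-clone event data.frames from
#'   [call_transitions()].
#' @param design an `NncnDesign`.
#' @param min_clones clone count required before an all-zero table is
#'   summarized as no detectable activity (default 20).
#' @return object of class `MotifFrequencyTable`: `table` (motif,
#'   n_sites, n_transitions, n_other, frequency, absent) plus
#'   `n_clones` and `no_detectable_activity`.
#' @export
motif_frequency_table <- function(events, design, min_clones = 20L) {
  stopifnot(inherits(design, "NncnDesign"))
  if (!length(events)) stop("no clone events supplied")
  pooled <- do.call(rbind, events)
  eligible <- pooled[pooled$event != "indel_adjacent", , drop = FALSE]
  motifs <- ALL_NNCN_MOTIFS()
  tab <- do.call(rbind, lapply(motifs, function(m) {
    sub <- eligible[eligible$context == m, , drop = FALSE]
    n_sites <- nrow(sub)
    n_tr <- sum(sub$event == "C->T")
    data.frame(motif = m, n_sites = n_sites, n_transitions = n_tr,
               n_other = sum(sub$event == "other_substitution"),
               frequency = if (n_sites > 0L) n_tr / n_sites else NA_real_,
               absent = n_sites == 0L, stringsAsFactors = FALSE)
  }))
  total_tr <- sum(tab$n_transitions)
  structure(list(table = tab, n_clones = length(events),
                 no_detectable_activity = total_tr == 0L &&
                   length(events) >= min_clones),
            class = "MotifFrequencyTable")
}

#' @export
print.MotifFrequencyTable <- function(x, ...) {
  cat("MotifFrequencyTable:", x$n_clones, "clones,",
      sum(x$table$n_transitions), "C->T transitions")
  if (x$no_detectable_activity) cat(" [no detectable activity]")
  cat("\n")
  invisible(x)
}

#' Write a motif frequency table to TSV
#' @param x a `MotifFrequencyTable`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_motif_frequency_table <- function(x, path) {
  utils::write.table(x$table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
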