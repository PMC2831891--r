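# default allowed residue counts between consecutive Cys of the
# four-disulfide-core grammar (C5 and C6 adjacent), patterned on the
# canonical WAP signature spacing
default_wap_spacing <- list(c(6, 9), c(5, 7), c(4, 6), c(3, 5),
                            c(0, 0), c(3, 5), c(3, 4))

wap_regex <- function(spacing) {
  if (length(spacing) != 7) abort("spacing profile needs 7 inter-Cys ranges")
  spacer <- vapply(spacing, function(r) {
    if (r[1] == 0 && r[2] == 0) "()" else sprintf("(.{%d,%d})", r[1], r[2])
  }, "")
  paste0("(C)", paste0(spacer, "(C)", collapse = ""))
}

#' Scan a peptide for WAP (four-disulfide core) domains
#'
#' Matches the eight-cysteine grammar `C-x(a1..b1)-C-...-C` with
#' configurable inter-cysteine spacing ranges; hits are reported
#' leftmost-first and non-overlapping.
#'
#' @param peptide Amino-acid string (may be empty).
#' @param spacing List of 7 `c(min, max)` residue-count ranges between
#'   consecutive cysteines.
#' @param catalytic_offset Optional 0-based offset from the hit start at
#'   which the catalytically important methionine is expected; when given,
#'   `met_at_catalytic` reports whether the residue there is `M`.
#' @return Tibble: `start`, `end` (0-based half-open on the peptide),
#'   `cys_positions` (list-column of eight 0-based positions),
#'   `met_at_catalytic`.
#' @export
find_wap <- function(peptide, spacing = default_wap_spacing,
                     catalytic_offset = NULL) {
  out <- tibble(start = integer(), end = integer(),
                cys_positions = list(), met_at_catalytic = logical())
  if (!nzchar(peptide)) return(out)
  peptide <- toupper(peptide)
  pat <- wap_regex(spacing)
  offset <- 0L
  repeat {
    rest <- substr(peptide, offset + 1L, nchar(peptide))
    m <- regexpr(pat, rest, perl = TRUE)
    if (m == -1) break
    cs <- attr(m, "capture.start")
    cl <- attr(m, "capture.length")
    # odd capture groups are the cysteines
    cysg <- seq(1, 15, by = 2)
    cys0 <- offset + cs[cysg] - 1L
    start <- cys0[1]
    end <- cys0[8] + 1L
    met <- if (is.null(catalytic_offset)) NA else
      substr(peptide, start + catalytic_offset + 1L,
             start + catalytic_offset + 1L) == "M"
    out <- bind_rows(out, tibble(start = start, end = end,
                                 cys_positions = list(as.integer(cys0)),
                                 met_at_catalytic = met))
    offset <- end
  }
  out
}

#' Classify WAP sequences by the catalytic-methionine ("Met") rule
#'
#' In an aligned set of WAP peptides, sequences holding a methionine at the
#' reference's catalytic column are labelled `trappin2_like`, the rest
#' `paralog_like`. The label is advisory: lineage assignment by noncoding
#' phylogeny can overrule it (known exceptions exist), so final naming is
#' the caller's job.
#'
#' @param aln Peptide [alignment()].
#' @param ref_id Id of the reference row (must carry `M` at the column).
#' @param catalytic_column 1-based alignment column of the reference's
#'   catalytic methionine.
#' @return Tibble `id`, `residue`, `label`, in input row order.
#' @export
classify_met_rule <- function(aln, ref_id, catalytic_column) {
  if (!ref_id %in% names(aln)) abort(paste0("ref_id not in alignment: ", ref_id))
  if (catalytic_column < 1 || catalytic_column > aln_width(aln))
    abort("catalytic_column out of range")
  res <- unname(substr(as.character(unclass(aln)), catalytic_column,
                       catalytic_column))
  if (res[[which(names(aln) == ref_id)]] != "M")
    abort(sprintf("reference %s has '%s', not M, at column %d: miscalibrated",
                  ref_id, res[[which(names(aln) == ref_id)]],
                  catalytic_column))
  tibble(id = names(aln), residue = res,
         label = ifelse(res == "M", "trappin2_like", "paralog_like"))
}

#' Find tandem repeats of the transglutaminase-substrate hexamer
#'
#' Maximal tandem runs of 6-residue units, each within `max_mismatch`
#' Hamming distance of the consensus (default `KGQDPV`). Units are exact
#' hexamer frames (no indels within a unit); runs are reported
#' leftmost-first and never overlap.
#'
#' @param peptide Amino-acid string.
#' @param consensus Repeat unit consensus.
#' @param max_mismatch Maximum mismatches per unit.
#' @param min_copies Minimum tandem copies to report.
#' @return Tibble: `start` (0-based), `copies`, `unit_length`,
#'   `mismatches` (list-column, one count per copy).
#' @export
find_tgs_repeats <- function(peptide, consensus = "KGQDPV",
                             max_mismatch = 2, min_copies = 2) {
  k <- nchar(consensus)
  out <- tibble(start = integer(), copies = integer(),
                unit_length = integer(), mismatches = list())
  n <- nchar(peptide)
  if (n < k * min_copies) return(out)
  pep <- strsplit(toupper(peptide), "")[[1]]
  cons <- strsplit(toupper(consensus), "")[[1]]
  nstart <- n - k + 1
  mm <- vapply(seq_len(nstart), function(s)
    sum(pep[s:(s + k - 1)] != cons), integer(1))
  ok <- mm <= max_mismatch
  runs <- list()
  for (s in seq_len(nstart)) {
    if (!ok[s]) next
    # maximal run starting at s within its frame: reject if the previous
    # in-frame unit also matches (not leftmost of its run)
    if (s - k >= 1 && ok[s - k]) next
    len <- 0L
    while (s + len * k <= nstart && ok[s + len * k]) len <- len + 1L
    if (len >= min_copies)
      runs <- c(runs, list(list(start = s - 1L, copies = len,
                                mism = mm[s + (0:(len - 1)) * k])))
  }
  if (!length(runs)) return(out)
  runs <- runs[order(vapply(runs, `[[`, 0L, "start"))]
  last_end <- -1L
  for (r in runs) {
    if (r$start < last_end) next  # keep leftmost of overlapping runs
    out <- bind_rows(out, tibble(start = r$start, copies = r$copies,
                                 unit_length = as.integer(k),
                                 mismatches = list(as.integer(r$mism))))
    last_end <- r$start + r$copies * k
  }
  out
}

#' Harr-plot dot matrix of two nucleotide sequences
#'
#' A dot marks every pair of window start positions `(i, j)` where at least
#' `stringency` of the `window` aligned residues agree (step 1, forward
#' strand only). The conventional setting for genomic comparisons is a
#' 23/40 stringency.
#'
#' @param seq_a,seq_b Ungapped nucleotide strings, each at least `window`
#'   long.
#' @param window Window length (nt).
#' @param stringency Minimum matching residues per window
#'   (`0 < stringency <= window`).
#' @return A `harr_plot` object; `$dots` is a tibble of 1-based window
#'   start coordinates `start_a`, `start_b` plus the match count.
#' @export
harr_plot <- function(seq_a, seq_b, window = 40, stringency = 23) {
  if (stringency <= 0 || stringency > window)
    abort("need 0 < stringency <= window")
  if (grepl("-", seq_a) || grepl("-", seq_b))
    abort("sequences must be ungapped")
  a <- strsplit(toupper(seq_a), "")[[1]]
  b <- strsplit(toupper(seq_b), "")[[1]]
  na <- length(a); nb <- length(b)
  if (na < window || nb < window)
    abort("sequences must be at least one window long")
  res <- list()
  for (d in (-(nb - window)):(na - window)) {
    ia <- max(1, 1 + d); ib <- ia - d
    len <- min(na - ia, nb - ib) + 1
    if (len < window) next
    eq <- a[ia:(ia + len - 1)] == b[ib:(ib + len - 1)]
    cs <- c(0, cumsum(eq))
    nw <- len - window + 1
    score <- cs[(window + 1):(window + nw)] - cs[1:nw]
    hit <- which(score >= stringency)
    if (length(hit))
      res[[length(res) + 1]] <- tibble(start_a = ia + hit - 1L,
                                       start_b = ib + hit - 1L,
                                       matches = score[hit])
  }
  dots <- if (length(res)) bind_rows(res) else
    tibble(start_a = integer(), start_b = integer(), matches = integer())
  dots <- arrange(dots, .data$start_a, .data$start_b)
  structure(list(dots = dots, window = window, stringency = stringency,
                 n_a = na, n_b = nb),
            class = "harr_plot")
}

#' @export
print.harr_plot <- function(x, ...) {
  cat(sprintf("<harr_plot> %d x %d nt, %d/%d stringency, %d dots\n",
              x$n_a, x$n_b, x$stringency, x$window, nrow(x$dots)))
  invisible(x)
}

#' @rdname harr_plot
#' @param object A `harr_plot`.
#' @param ... Unused.
#' @export
autoplot.harr_plot <- function(object, ...) {
  ggplot2::ggplot(object$dots,
                  ggplot2::aes(x = .data$start_a, y = .data$start_b)) +
    ggplot2::geom_point(size = 0.3) +
    ggplot2::coord_fixed(xlim = c(1, object$n_a), ylim = c(1, object$n_b)) +
    ggplot2::labs(x = "sequence A (window start, nt)",
                  y = "sequence B (window start, nt)",
                  title = sprintf("Harr plot, %d/%d stringency",
                                  object$stringency, object$window)) +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
NULL
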