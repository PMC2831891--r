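#' Gap-aware sequence alignments
#'
#' A `seq_alignment` is a named character vector of equal-length gapped
#' sequences (rows), with attributes recording the residue type (`"dna"` or
#' `"aa"`), whether rows are in codon frame, and an optional region name.
#' The gap character is `-`; `N` (nucleotide) and `X` (peptide) are treated
#' as missing data.
#'
#' @param seqs Named character vector of aligned rows (equal lengths).
#' @param type `"dna"` or `"aa"`.
#' @param is_codon Logical; if `TRUE` every row's ungapped length must be a
#'   multiple of three.
#' @param region Optional region label carried along by [slice_region()].
#' @return A `seq_alignment` object.
#' @examples
#' alignment(c(g1 = "ACGT", g2 = "AC-T"))
#' @export
alignment <- function(seqs, type = c("dna", "aa"), is_codon = FALSE,
                      region = NA_character_) {
  type <- match.arg(type)
  if (length(seqs) == 0) abort("alignment needs at least one sequence")
  if (is.null(names(seqs)) || any(names(seqs) == ""))
    abort("all alignment rows must be named")
  if (anyDuplicated(names(seqs)))
    abort(paste0("duplicate sequence ids: ",
                 paste(unique(names(seqs)[duplicated(names(seqs))]),
                       collapse = ", ")))
  seqs <- toupper(seqs)
  w <- nchar(seqs)
  if (length(unique(w)) != 1)
    abort("ragged alignment: rows have unequal lengths")
  allowed <- if (type == "dna") "ACGTN-" else
    paste0(paste(strsplit("ACDEFGHIKLMNPQRSTVWYXBZU*", "")[[1]], collapse = ""), "-")
  bad <- grepl(sprintf("[^%s]", allowed), seqs)
  if (any(bad))
    abort(paste0("invalid ", type, " characters in rows: ",
                 paste(names(seqs)[bad], collapse = ", ")))
  if (is_codon) {
    ug <- nchar(gsub("-", "", seqs))
    if (any(ug %% 3 != 0))
      abort("codon alignment: ungapped row length not divisible by 3")
  }
  structure(seqs, class = "seq_alignment", aln_type = type,
            is_codon = is_codon, region = region)
}

#' @export
print.seq_alignment <- function(x, ...) {
  cat(sprintf("<seq_alignment> %d x %d (%s%s)%s\n",
              length(x), nchar(x[[1]]), attr(x, "aln_type"),
              if (isTRUE(attr(x, "is_codon"))) ", codon" else "",
              if (!is.na(attr(x, "region") %||% NA))
                paste0(" region=", attr(x, "region")) else ""))
  show <- utils::head(unclass(x), 8)
  for (i in seq_along(show))
    cat(sprintf("  %-12s %s\n", names(show)[i],
                if (nchar(show[i]) > 60)
                  paste0(substr(show[i], 1, 57), "...") else show[i]))
  if (length(x) > 8) cat(sprintf("  ... %d more rows\n", length(x) - 8))
  invisible(x)
}

aln_width <- function(aln) nchar(aln[[1]])

# character matrix view, rows = sequences
aln_matrix <- function(aln) {
  m <- do.call(rbind, strsplit(unclass(aln), ""))
  rownames(m) <- names(aln)
  m
}

aln_from_matrix <- function(m, template) {
  seqs <- apply(m, 1, paste, collapse = "")
  if (ncol(m) == 0) seqs <- stats::setNames(rep("", nrow(m)), rownames(m))
  names(seqs) <- rownames(m)
  structure(seqs, class = "seq_alignment",
            aln_type = attr(template, "aln_type"),
            is_codon = attr(template, "is_codon"),
            region = attr(template, "region"))
}

#' Read an aligned FASTA file
#'
#' Residues are uppercased; rows must have identical lengths and unique ids.
#'
#' @param path FASTA file.
#' @param type `"dna"` or `"aa"`.
#' @return A [alignment()] object, rows in input order.
#' @export
read_aligned_fasta <- function(path, type = c("dna", "aa")) {
  type <- match.arg(type)
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  lines <- readLines(path, warn = FALSE)
  if (any(startsWith(lines, ";"))) {   # strip classic-FASTA comment lines
    path <- tempfile(fileext = ".fasta")
    writeLines(lines[!startsWith(lines, ";")], path)
  }
  ss <- tryCatch(Biostrings::readBStringSet(path),
                 error = function(e) abort(paste0("FASTA parse error in ",
                                                  path, ": ", conditionMessage(e))))
  if (length(ss) == 0) abort(paste0("empty FASTA file: ", path))
  if (length(unique(Biostrings::width(ss))) != 1)
    abort(paste0("ragged alignment in ", path, ": unequal row lengths"))
  ids <- sub("\\s.*$", "", names(ss))
  seqs <- stats::setNames(as.character(ss), ids)
  alignment(seqs, type = type)
}

#' Write an alignment as FASTA
#'
#' @param aln A [alignment()] object.
#' @param path Output file.
#' @param header Optional comment line (written as `; header` before records).
#' @export
write_aligned_fasta <- function(aln, path, header = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("; ", header), con)
  for (i in seq_along(aln))
    writeLines(c(paste0(">", names(aln)[i]), unclass(aln)[[i]]), con)
  invisible(path)
}

canonical_regions <- c("flank5", "exon1", "intron1", "exon2", "intron2",
                       "exon3", "flank3")
coding_subregions <- c("signal", "TGS", "WAP")

#' Read a per-gene region table
#'
#' Tab-separated file with header `gene_id  region  start  end`; coordinates
#' are 0-based half-open on the ungapped gene sequence. Top-level regions of
#' one gene may not overlap; the coding subregions `signal`, `TGS` and `WAP`
#' must nest inside a top-level exon.
#'
#' @param path TSV file.
#' @return Tibble with columns `gene_id`, `region`, `start`, `end`.
#' @export
read_region_table <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  tbl <- readr::read_tsv(path, show_col_types = FALSE,
                         comment = "#", progress = FALSE)
  need <- c("gene_id", "region", "start", "end")
  if (!all(need %in% names(tbl)))
    abort(paste0("region table must have columns: ", paste(need, collapse = ", ")))
  tbl <- tbl[need]
  validate_region_table(tbl)
  tbl
}

#' Validate a region table
#'
#' @param tbl Tibble as returned by [read_region_table()].
#' @return The table, invisibly; errors name the offending gene and region.
#' @export
validate_region_table <- function(tbl) {
  if (any(tbl$start >= tbl$end)) {
    bad <- tbl[tbl$start >= tbl$end, ]
    abort(sprintf("empty/inverted interval for gene %s region %s",
                  bad$gene_id[1], bad$region[1]))
  }
  if (any(tbl$start < 0)) abort("negative region start")
  for (g in unique(tbl$gene_id)) {
    sub <- tbl[tbl$gene_id == g, ]
    top <- sub[!(sub$region %in% coding_subregions), ]
    top <- top[order(top$start), ]
    if (nrow(top) > 1) {
      ov <- which(top$start[-1] < top$end[-nrow(top)])
      if (length(ov))
        abort(sprintf("overlapping regions for gene %s: %s and %s",
                      g, top$region[ov[1]], top$region[ov[1] + 1]))
    }
    nested <- sub[sub$region %in% coding_subregions, ]
    if (nrow(nested)) {
      for (k in seq_len(nrow(nested))) {
        host <- top$start <= nested$start[k] & top$end >= nested$end[k] &
          top$region %in% c("exon1", "exon2")
        if (!any(host))
          abort(sprintf(
            "coding subregion %s of gene %s does not nest inside exon1/exon2",
            nested$region[k], g))
      }
    }
  }
  invisible(tbl)
}

# tibble of (region,start,end) for one gene; errors if region missing
gene_region <- function(regions, gene_id, region_name) {
  r <- regions[regions$gene_id == gene_id & regions$region == region_name, ]
  if (nrow(r) == 0) return(NULL)
  r[1, ]
}

#' Extract the alignment columns of one annotated region
#'
#' Region coordinates refer to 0-based ungapped positions of each gene. A
#' column is kept when its ungapped position falls inside the named region's
#' interval in *every* row (the intersection). For a gap character the
#' position of the next non-gap residue is used, so gap columns interior to
#' a region are retained; deciding what to do with them is left to
#' [complete_deletion()].
#'
#' @param aln A [alignment()] object of full-length genes.
#' @param regions Region tibble (see [read_region_table()]).
#' @param region_name Region to extract. The pseudo-region `"noncoding"`
#'   concatenates flank5, intron1, intron2, exon3 and flank3, mirroring the
#'   "entire gene except coding region" row of regional rate tables.
#' @param is_codon Mark the result as codon-framed.
#' @return A `seq_alignment` restricted to the region's columns.
#' @export
slice_region <- function(aln, regions, region_name, is_codon = FALSE) {
  if (identical(region_name, "noncoding")) {
    parts <- lapply(noncoding_region_names, function(r) {
      if (all(vapply(names(aln), function(g)
        !is.null(gene_region(regions, g, r)), TRUE)))
        slice_region(aln, regions, r) else NULL
    })
    parts <- parts[!vapply(parts, is.null, TRUE)]
    if (!length(parts)) abort("no noncoding regions annotated")
    return(concat_alignments(parts, region = "noncoding"))
  }
  missing_ids <- names(aln)[vapply(names(aln), function(g)
    is.null(gene_region(regions, g, region_name)), TRUE)]
  if (length(missing_ids))
    abort(sprintf("region '%s' not annotated for: %s", region_name,
                  paste(missing_ids, collapse = ", ")))
  m <- aln_matrix(aln)
  keep <- rep(TRUE, ncol(m))
  for (i in seq_len(nrow(m))) {
    r <- gene_region(regions, rownames(m)[i], region_name)
    row <- m[i, ]
    nongap <- row != "-"
    if (sum(nongap) < r$end)
      abort(sprintf("region %s [%d,%d) out of range for gene %s (%d nt)",
                    region_name, r$start, r$end, rownames(m)[i], sum(nongap)))
    cums <- cumsum(nongap)
    pos <- ifelse(nongap, cums - 1L, cums)   # gap -> index of next residue
    keep <- keep & pos >= r$start & pos < r$end
  }
  out <- aln_from_matrix(m[, keep, drop = FALSE], aln)
  attr(out, "region") <- region_name
  attr(out, "is_codon") <- is_codon
  out
}

noncoding_region_names <- c("flank5", "intron1", "intron2", "exon3", "flank3")

# column-wise concatenation of alignments over the same ids
concat_alignments <- function(alns, region = NA_character_) {
  ids <- names(alns[[1]])
  for (a in alns)
    if (!identical(sort(names(a)), sort(ids)))
      abort("cannot concatenate alignments with different ids")
  seqs <- vapply(ids, function(g)
    paste(vapply(alns, function(a) unclass(a)[[g]], ""), collapse = ""), "")
  out <- alignment(stats::setNames(seqs, ids),
                   type = attr(alns[[1]], "aln_type"))
  attr(out, "region") <- region
  out
}

#' Remove all columns containing gaps or missing data
#'
#' Complete deletion: drops every column in which any row holds `-`, `N`
#' (nucleotide) or `X` (peptide). The number of removed columns is recorded
#' in attribute `"removed"`.
#'
#' @param aln A [alignment()] object.
#' @return The filtered alignment (possibly zero columns).
#' @export
complete_deletion <- function(aln) {
  m <- aln_matrix(aln)
  missing_chars <- if (attr(aln, "aln_type") == "dna") c("-", "N", "?")
                   else c("-", "X", "?")
  keep <- !apply(matrix(m %in% missing_chars, nrow(m)), 2, any)
  out <- aln_from_matrix(m[, keep, drop = FALSE], aln)
  attr(out, "removed") <- sum(!keep)
  out
}

#' Read / write trees in newick format
#'
#' Thin wrappers over \pkg{ape} that preserve branch lengths and internal
#' node support labels on round-trip.
#'
#' @param path Newick file.
#' @return `read_newick()`: an `ape::phylo`; `write_newick()`: the path,
#'   invisibly.
#' @export
read_newick <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  txt <- paste(readLines(path, warn = FALSE), collapse = "")
  if (!nzchar(gsub("\\s", "", txt))) abort(paste0("empty newick file: ", path))
  op <- lengths(regmatches(txt, gregexpr("\\(", txt)))
  cl <- lengths(regmatches(txt, gregexpr("\\)", txt)))
  if (op != cl)
    abort(sprintf("malformed newick in %s: %d '(' vs %d ')'", path, op, cl))
  tr <- tryCatch(ape::read.tree(text = txt), error = function(e) NULL,
                 warning = function(w) NULL)
  if (is.null(tr)) abort(paste0("malformed newick in ", path))
  if (anyDuplicated(tr$tip.label)) abort("duplicate leaf labels in tree")
  tr
}

#' @rdname read_newick
#' @param tree An `ape::phylo`.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path, digits = 10)
  invisible(path)
}

#' Optimal global pairwise alignment (Needleman-Wunsch, linear gap penalty)
#'
#' Plumbing used to pair a cDNA with its concatenated genomic exons before
#' substitution counting. Ties in the dynamic program are broken
#' deterministically: diagonal (match/mismatch) is preferred, then up (gap in
#' `b`), then left.
#'
#' @param a,b Ungapped nucleotide strings.
#' @param match,mismatch,gap Scores (gap is per-residue, linear).
#' @return List with gapped strings `a`, `b` and the optimal `score`.
#' @export
global_pairwise_align <- function(a, b, match = 1, mismatch = -1, gap = -2) {
  if (!nzchar(a) || !nzchar(b)) abort("empty sequence in pairwise alignment")
  av <- strsplit(toupper(a), "")[[1]]
  bv <- strsplit(toupper(b), "")[[1]]
  n <- length(av); m <- length(bv)
  S <- matrix(0, n + 1, m + 1)
  S[, 1] <- gap * (0:n)
  S[1, ] <- gap * (0:m)
  # direction: 1 diag, 2 up (consume a), 3 left (consume b)
  D <- matrix(0L, n + 1, m + 1)
  D[, 1][-1] <- 2L
  D[1, ][-1] <- 3L
  for (i in 1:n) {
    sub <- ifelse(bv == av[i], match, mismatch)
    prev <- S[i, ]
    cur <- numeric(m + 1)
    cur[1] <- gap * i
    for (j in 1:m) {
      diag <- prev[j] + sub[j]
      up <- prev[j + 1] + gap
      left <- cur[j] + gap
      best <- max(diag, up, left)
      cur[j + 1] <- best
      D[i + 1, j + 1] <- if (diag == best) 1L else if (up == best) 2L else 3L
    }
    S[i + 1, ] <- cur
  }
  ga <- character(0); gb <- character(0)
  i <- n + 1; j <- m + 1
  while (i > 1 || j > 1) {
    d <- D[i, j]
    if (d == 1L) {
      ga <- c(av[i - 1], ga); gb <- c(bv[j - 1], gb); i <- i - 1; j <- j - 1
    } else if (d == 2L) {
      ga <- c(av[i - 1], ga); gb <- c("-", gb); i <- i - 1
    } else {
      ga <- c("-", ga); gb <- c(bv[j - 1], gb); j <- j - 1
    }
  }
  list(a = paste(ga, collapse = ""), b = paste(gb, collapse = ""),
       score = S[n + 1, m + 1])
}
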