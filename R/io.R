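## Readers/writers and tree-time utilities shared by every downstream stage.
## Sequences are represented throughout as a named character vector
## (names = sequence ids, values = uppercase nucleotide strings).

MISSING_CHARS <- c("-", "N", "?")

#' Read an aligned FASTA file
#'
#' Sequences are uppercased on input.  When `as_alignment = TRUE` (default)
#' all sequences must have equal length; a ragged set is an error because
#' every downstream statistic assumes positional homology.
#'
#' @param path Path to a FASTA file (wrapped or unwrapped).
#' @param as_alignment Enforce equal sequence lengths.
#' @return Named character vector of uppercase sequences.
#' @export
read_fasta <- function(path, as_alignment = TRUE) {
  if (!file.exists(path))
    stop_discretus("file_error", sprintf("FASTA file not found: %s", path))
  x <- Biostrings::readBStringSet(path)
  if (length(x) == 0L)
    stop_discretus("empty_input_error", sprintf("no sequences in %s", path))
  seqs <- toupper(as.character(x))
  names(seqs) <- sub("\\s.*$", "", names(x))  # id = first whitespace token
  if (anyDuplicated(names(seqs)))
    stop_discretus("duplicate_id_error", "duplicated sequence ids in FASTA")
  if (as_alignment) check_alignment(seqs)
  seqs
}

#' Write sequences to FASTA
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

check_alignment <- function(seqs) {
  if (length(seqs) == 0L)
    stop_discretus("empty_input_error", "empty alignment")
  len <- nchar(seqs)
  if (length(unique(len)) != 1L)
    stop_discretus("alignment_length_error",
                   sprintf("ragged alignment: lengths %s",
                           paste(unique(len), collapse = ", ")))
  invisible(seqs)
}

#' Collapse identical sequences into unique haplotypes
#'
#' Haplotype identity is exact string equality after uppercasing; gaps and
#' IUPAC ambiguity codes count as ordinary (differing) characters.  The
#' retained id is the first-seen id of each haplotype class.
#'
#' @param seqs Named character vector (an alignment).
#' @return Object of class `haplotype_alignment`: list with `seqs` (retained
#'   haplotypes), `multiplicity` (named integer, counts of raw sequences per
#'   haplotype) and `members` (named list of raw ids per haplotype).
#' @export
collapse_haplotypes <- function(seqs) {
  check_alignment(seqs)
  seqs <- toupper(seqs)
  first <- !duplicated(seqs)
  key <- match(seqs, seqs[first])
  hap_ids <- names(seqs)[first]
  multiplicity <- as.integer(tabulate(key, nbins = sum(first)))
  names(multiplicity) <- hap_ids
  members <- split(names(seqs), hap_ids[key])[hap_ids]
  structure(list(seqs = setNames(seqs[first], hap_ids),
                 multiplicity = multiplicity,
                 members = members),
            class = "haplotype_alignment")
}

#' @export
print.haplotype_alignment <- function(x, ...) {
  cat(sprintf("haplotype alignment: %d haplotypes from %d sequences (%d sites)\n",
              length(x$seqs), sum(x$multiplicity), nchar(x$seqs[[1]])))
  invisible(x)
}

## Encode an alignment as an integer matrix; 0 marks missing (gap/N/?).
encode_alignment <- function(seqs) {
  check_alignment(seqs)
  chars <- strsplit(toupper(seqs), "", fixed = TRUE)
  m <- matrix(unlist(chars), nrow = length(seqs), byrow = TRUE,
              dimnames = list(names(seqs), NULL))
  alphabet <- setdiff(sort(unique(as.vector(m))), MISSING_CHARS)
  code <- match(m, alphabet, nomatch = 0L)
  dim(code) <- dim(m)
  dimnames(code) <- dimnames(m)
  code
}

#' Raw p-distance matrix under pairwise deletion
#'
#' Proportion of differing sites per pair, ignoring (pairwise) any site where
#' either sequence has a gap, `N` or `?`.  A pair with zero comparable sites
#' yields `NA` with a warning.
#'
#' @param x Named character vector of aligned sequences, or a
#'   `haplotype_alignment`.
#' @return Symmetric numeric matrix with zero diagonal.
#' @export
p_distance_matrix <- function(x) {
  if (inherits(x, "haplotype_alignment")) x <- x$seqs
  if (length(x) < 2L)
    stop_discretus("insufficient_data_error", "need >= 2 sequences")
  code <- encode_alignment(x)
  n <- nrow(code)
  d <- matrix(0, n, n, dimnames = list(rownames(code), rownames(code)))
  any_na <- FALSE
  for (i in seq_len(n - 1L)) {
    ci <- code[i, ]
    for (j in (i + 1L):n) {
      cj <- code[j, ]
      ok <- ci > 0L & cj > 0L
      nc <- sum(ok)
      if (nc == 0L) {
        d[i, j] <- d[j, i] <- NA_real_
        any_na <- TRUE
      } else {
        d[i, j] <- d[j, i] <- sum(ci[ok] != cj[ok]) / nc
      }
    }
  }
  if (any_na)
    warn_discretus("undefined_distance_warning",
                   "some pairs share no comparable sites; distance set to NA")
  d
}

#' Read and validate an ultrametric binary tree
#'
#' Polytomies are rejected (dichotomy is a prerequisite for the branching-rate
#' models downstream) and ultrametricity is validated within a relative
#' tolerance on the root-to-tip spread.  Trees failing validation are
#' rejected, never rescaled.
#'
#' @param path Path to a Newick file (or `NULL` when `text` is given).
#' @param text Newick string, alternative to `path`.
#' @param tolerance Permitted relative root-to-tip spread (default `1e-6`).
#' @return An object of class `phylo`, validated.
#' @export
read_newick <- function(path = NULL, text = NULL, tolerance = 1e-6) {
  tr <- if (!is.null(text)) ape::read.tree(text = text) else {
    if (!file.exists(path))
      stop_discretus("file_error", sprintf("tree file not found: %s", path))
    ape::read.tree(path)
  }
  if (is.null(tr))
    stop_discretus("parse_error", "could not parse Newick input")
  if (inherits(tr, "multiPhylo")) {
    if (length(tr) != 1L)
      stop_discretus("parse_error", "expected exactly one tree")
    tr <- tr[[1L]]
  }
  validate_ultrametric(tr, tolerance)
}

#' Validate a phylo object as rooted, binary and ultrametric
#'
#' @param tr A `phylo` object.
#' @param tolerance Relative root-to-tip spread allowed.
#' @return `tr`, invisibly classed as valid (returned unchanged).
#' @export
validate_ultrametric <- function(tr, tolerance = 1e-6) {
  if (!inherits(tr, "phylo"))
    stop_discretus("type_error", "not a phylo object")
  if (is.null(tr$edge.length))
    stop_discretus("parse_error", "tree has no branch lengths")
  if (any(tr$edge.length < 0))
    stop_discretus("negative_branch_error", "negative branch lengths")
  if (!ape::is.rooted(tr))
    stop_discretus("non_binary_error", "tree is not rooted")
  if (!ape::is.binary(tr))
    stop_discretus("non_binary_error", "tree contains polytomies")
  depth <- ape::node.depth.edgelength(tr)
  tipd <- depth[seq_len(ape::Ntip(tr))]
  spread <- (max(tipd) - min(tipd)) / max(tipd)
  if (!is.finite(spread) || spread > tolerance)
    stop_discretus("non_ultrametric_error",
                   sprintf("root-to-tip spread %.3g exceeds tolerance %.3g",
                           spread, tolerance))
  tr
}

#' Node ages, branching times and inter-node intervals
#'
#' Ages are measured backwards from the present (tips at 0).  The intervals
#' table partitions `[0, root age]`; during the interval below the k-th
#' oldest branching event, `k + 1` lineages are present.
#'
#' @param tr Validated ultrametric `phylo`.
#' @return List with `ages` (named, internal nodes), `branching_times`
#'   (descending), and `intervals` (data.frame: start_age, end_age, width,
#'   n_lineages).
#' @export
node_times <- function(tr) {
  ages <- ape::branching.times(tr)
  bt <- sort(ages, decreasing = TRUE)
  k <- length(bt)
  start <- as.numeric(bt)
  end <- c(as.numeric(bt[-1L]), 0)
  intervals <- data.frame(start_age = start, end_age = end,
                          width = start - end,
                          n_lineages = seq_len(k) + 1L)
  list(ages = ages, branching_times = bt, intervals = intervals)
}

#' Patristic distance between two tips
#'
#' Sum of edge lengths along the path; on an ultrametric tree this equals
#' twice the age of the pair's most recent common ancestor.
#'
#' @param tr A `phylo`.
#' @param a,b Tip labels.
#' @return Numeric distance (same units as branch lengths).
#' @export
patristic_distance <- function(tr, a, b) {
  ia <- match(a, tr$tip.label)
  ib <- match(b, tr$tip.label)
  if (is.na(ia) || is.na(ib))
    stop_discretus("lookup_error",
                   sprintf("unknown tip label(s): %s",
                           paste(c(a, b)[is.na(c(ia, ib))], collapse = ", ")))
  if (ia == ib) return(0)
  ape::dist.nodes(tr)[ia, ib]
}

#' Full patristic distance matrix for the tips of a tree
#' @param tr A `phylo`.
#' @return Symmetric matrix labelled by tip.
#' @export
patristic_matrix <- function(tr) {
  stats::cophenetic(tr)
}

#' Read a per-sequence metadata table
#'
#' Tab-separated with header; required columns: `id`, `dataset`, `clade`,
#' `habitat`, `seq_length`.
#'
#' @param path Path to a TSV file.
#' @return data.frame.
#' @export
read_metadata <- function(path) {
  if (!file.exists(path))
    stop_discretus("file_error", sprintf("metadata file not found: %s", path))
  m <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("id", "dataset", "clade", "habitat", "seq_length")
  missing <- setdiff(need, names(m))
  if (length(missing))
    stop_discretus("metadata_error",
                   sprintf("metadata missing column(s): %s",
                           paste(missing, collapse = ", ")))
  if (anyDuplicated(m$id))
    stop_discretus("metadata_error", "duplicated ids in metadata")
  m
}

#' Check that tree tips and alignment ids match exactly
#'
#' The join is exact and case-sensitive; any mismatch is an error.
#'
#' @param tr A `phylo`.
#' @param seqs Named character vector of sequences.
#' @return `TRUE` invisibly.
#' @export
check_tip_join <- function(tr, seqs) {
  miss <- setdiff(tr$tip.label, names(seqs))
  if (length(miss))
    stop_discretus("lookup_error",
                   sprintf("tree tips missing from alignment: %s",
                           paste(head(miss, 5L), collapse = ", ")))
  invisible(TRUE)
}
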