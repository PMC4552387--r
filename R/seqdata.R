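# Alignment input, validation and haplotype collapsing.

IUPAC_DNA <- c("A", "C", "G", "T", "U", "R", "Y", "S", "W", "K", "M",
               "B", "D", "H", "V", "N", "-", "?")
DNA_BASES <- c("A", "C", "G", "T")

#' Construct a validated sequence alignment
#'
#' An alignment is stored as an n x L character matrix over the IUPAC DNA
#' alphabet (plus gap `-` and missing `N`/`?`), with unique sample ids as row
#' names. All sequences must have equal length.
#'
#' @param sequences named character vector of equal-length DNA strings, or a
#'   character matrix with one row per sample and one column per site.
#' @param ids sample identifiers; defaults to the names of `sequences`.
#' @return an object of class `seq_alignment`: a list with elements `ids`,
#'   `seqs` (character matrix, upper case), `n` and `L`.
#' @export
seq_alignment <- function(sequences, ids = NULL) {
  if (is.matrix(sequences)) {
    mat <- toupper(sequences)
    if (is.null(ids)) ids <- rownames(sequences)
  } else {
    if (is.null(ids)) ids <- names(sequences)
    sequences <- as.character(sequences)
    if (is.null(ids)) stop("sample ids are required", call. = FALSE)
    if (length(sequences) == 0L) stop("empty alignment", call. = FALSE)
    lens <- nchar(sequences)
    if (length(unique(lens)) != 1L) {
      stop(sprintf("ragged alignment: sequence lengths %s",
                   paste(unique(lens), collapse = ", ")), call. = FALSE)
    }
    if (lens[1] == 0L) stop("empty alignment: zero-length sequences", call. = FALSE)
    mat <- matrix(toupper(unlist(strsplit(sequences, "", fixed = TRUE))),
                  nrow = length(sequences), byrow = TRUE)
  }
  if (nrow(mat) == 0L || ncol(mat) == 0L) stop("empty alignment", call. = FALSE)
  ids <- as.character(ids)
  if (anyDuplicated(ids)) stop("duplicate sample ids", call. = FALSE)
  if (length(ids) != nrow(mat)) stop("ids do not match number of sequences", call. = FALSE)
  bad <- !(mat %in% IUPAC_DNA)
  if (any(bad)) {
    idx <- which(matrix(bad, nrow(mat), ncol(mat)), arr.ind = TRUE)[1, ]
    stop(sprintf("illegal symbol '%s' in sequence '%s' at site %d",
                 mat[idx[1], idx[2]], ids[idx[1]], idx[2]), call. = FALSE)
  }
  rownames(mat) <- ids
  structure(list(ids = ids, seqs = mat, n = nrow(mat), L = ncol(mat)),
            class = "seq_alignment")
}

#' Read a multi-FASTA alignment
#'
#' @param path path to a FASTA file (wrapped or unwrapped records).
#' @return a [seq_alignment()] object.
#' @export
read_alignment <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  ss <- tryCatch(Biostrings::readBStringSet(path),
                 error = function(e) stop("unparseable FASTA: ", conditionMessage(e),
                                          call. = FALSE))
  if (length(ss) == 0L) stop("empty FASTA file: ", path, call. = FALSE)
  seqs <- as.character(ss)
  names(seqs) <- sub("\\s.*$", "", names(ss))
  seq_alignment(seqs)
}

#' @export
print.seq_alignment <- function(x, ...) {
  cat(sprintf("seq_alignment: %d sequences, %d sites\n", x$n, x$L))
  invisible(x)
}

#' Read a sample metadata table
#'
#' Tab-separated table with header columns `sample_id`, `population`, `group`
#' and optionally `region` and `paic` (used by the tree-hypothesis
#' classifier). Each population must nest in exactly one group.
#'
#' @param path path to the TSV file.
#' @return data frame with one row per sample.
#' @export
read_sample_metadata <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  validate_grouping(df)
  df
}

validate_grouping <- function(df) {
  need <- c("sample_id", "population", "group")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("metadata missing columns: ", paste(miss, collapse = ", "),
                         call. = FALSE)
  if (anyDuplicated(df$sample_id)) stop("duplicate sample_id in metadata", call. = FALSE)
  nest <- unique(df[, c("population", "group")])
  if (anyDuplicated(nest$population)) {
    stop("population assigned to more than one group", call. = FALSE)
  }
  invisible(df)
}

check_grouping <- function(aln, grouping) {
  validate_grouping(grouping)
  unmapped <- setdiff(aln$ids, grouping$sample_id)
  if (length(unmapped)) {
    stop("samples missing from metadata: ", paste(unmapped, collapse = ", "),
         call. = FALSE)
  }
  grouping[match(aln$ids, grouping$sample_id), , drop = FALSE]
}

#' Restrict an alignment to unambiguous sites
#'
#' Under the default complete-deletion policy every site containing a gap,
#' `N`/`?` or an IUPAC ambiguity code in any sequence is removed, fixing one
#' deterministic site set for all downstream statistics. Ambiguity codes are
#' treated as missing: for an effectively haploid mitochondrial marker they
#' represent uncertain reads, not heterozygotes.
#'
#' @param aln a [seq_alignment()].
#' @return a `seq_alignment` on the retained sites, with attribute
#'   `kept_sites` giving the original site indices.
#' @export
filter_complete_sites <- function(aln) {
  keep <- apply(aln$seqs, 2, function(col) all(col %in% DNA_BASES))
  out <- seq_alignment(aln$seqs[, keep, drop = FALSE], ids = aln$ids)
  attr(out, "kept_sites") <- which(keep)
  out
}

# TRUE when two sequences are identical at all mutually determined sites.
pairwise_compatible <- function(a, b) {
  ok <- a %in% DNA_BASES & b %in% DNA_BASES
  !any(a[ok] != b[ok])
}

#' Collapse aligned sequences into haplotypes
#'
#' Sequences identical under the site policy share one haplotype; counts are
#' partitioned by population. With `site_policy = "complete"` (default) the
#' alignment is first restricted to sites with an unambiguous base in every
#' sequence, and identity is exact string equality on that site set. With
#' `site_policy = "pairwise"` two sequences are merged when they conflict at
#' no mutually determined site (transitively closed); this keeps more sites
#' but the relation is not guaranteed transitive, so the complete-deletion
#' policy is the default.
#'
#' @param aln a [seq_alignment()].
#' @param grouping metadata data frame (`sample_id`, `population`, `group`);
#'   if `NULL` all samples form a single population.
#' @param site_policy `"complete"` or `"pairwise"`.
#' @return an object of class `haplotype_table`: list with `haplotypes`
#'   (character vector of collapsed sequences over the retained sites),
#'   `counts` (haplotype x population matrix), `freq`, `h`, `n`,
#'   `L_eff` (number of retained sites), `members` (sample ids per
#'   haplotype) and `site_policy`.
#' @export
collapse_haplotypes <- function(aln, grouping = NULL,
                                site_policy = c("complete", "pairwise")) {
  site_policy <- match.arg(site_policy)
  if (is.null(grouping)) {
    grouping <- data.frame(sample_id = aln$ids, population = "pop1",
                           group = "group1", stringsAsFactors = FALSE)
  }
  grouping <- check_grouping(aln, grouping)

  if (site_policy == "complete") {
    core <- filter_complete_sites(aln)
    strs <- apply(core$seqs, 1, paste, collapse = "")
    hap_of <- match(strs, unique(strs))
    hap_seq <- unique(strs)
    L_eff <- core$L
  } else {
    n <- aln$n
    parent <- seq_len(n)
    find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      if (pairwise_compatible(aln$seqs[i, ], aln$seqs[j, ])) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
      }
    }
    roots <- vapply(seq_len(n), find, integer(1))
    hap_of <- match(roots, unique(roots))
    # representative sequence: site-wise consensus of determined states
    hap_seq <- vapply(unique(roots), function(r) {
      rows <- aln$seqs[roots == r, , drop = FALSE]
      paste(apply(rows, 2, function(col) {
        det <- col[col %in% DNA_BASES]
        if (length(det)) det[1] else "N"
      }), collapse = "")
    }, character(1))
    L_eff <- aln$L
  }

  pops <- sort(unique(grouping$population))
  counts <- matrix(0L, nrow = length(hap_seq), ncol = length(pops),
                   dimnames = list(paste0("H", seq_along(hap_seq)), pops))
  for (i in seq_len(aln$n)) {
    counts[hap_of[i], grouping$population[i]] <- counts[hap_of[i], grouping$population[i]] + 1L
  }
  members <- split(aln$ids, hap_of)
  names(members) <- rownames(counts)
  n <- sum(counts)
  structure(list(haplotypes = hap_seq, counts = counts,
                 freq = rowSums(counts) / n, h = length(hap_seq), n = n,
                 L_eff = L_eff, members = members, site_policy = site_policy,
                 assignment = stats::setNames(hap_of, aln$ids)),
            class = "haplotype_table")
}

#' @export
print.haplotype_table <- function(x, ...) {
  cat(sprintf("haplotype_table: %d haplotypes among %d samples (%d sites, %s policy)\n",
              x$h, x$n, x$L_eff, x$site_policy))
  invisible(x)
}

#' Expand a haplotype table back to per-sample sequences
#'
#' Inverse of [collapse_haplotypes()] up to sample naming; used to check that
#' collapsing is idempotent.
#'
#' @param tab a `haplotype_table`.
#' @return list with a [seq_alignment()] and the matching grouping data frame.
#' @export
expand_haplotypes <- function(tab) {
  seqs <- character(0); ids <- character(0); pop <- character(0)
  k <- 0L
  for (hi in seq_len(tab$h)) for (pj in colnames(tab$counts)) {
    cnt <- tab$counts[hi, pj]
    if (cnt > 0) for (r in seq_len(cnt)) {
      k <- k + 1L
      ids <- c(ids, sprintf("s%03d", k))
      seqs <- c(seqs, tab$haplotypes[hi])
      pop <- c(pop, pj)
    }
  }
  list(aln = seq_alignment(stats::setNames(seqs, ids)),
       grouping = data.frame(sample_id = ids, population = pop,
                             group = "group1", stringsAsFactors = FALSE))
}

#' Write a haplotype table as TSV
#'
#' @param tab a `haplotype_table`.
#' @param path output file.
#' @export
write_haplotype_table <- function(tab, path) {
  df <- data.frame(haplotype = rownames(tab$counts),
                   sequence = tab$haplotypes,
                   tab$counts, total = rowSums(tab$counts),
                   freq = tab$freq, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write an alignment as FASTA
#'
#' @param aln a [seq_alignment()].
#' @param path output file.
#' @export
write_alignment <- function(aln, path) {
  bin <- ape::as.DNAbin(aln$seqs)
  ape::write.FASTA(bin, path)
  invisible(path)
}

# Extract the character submatrix for one population.
pop_matrix <- function(aln, grouping, population) {
  grouping <- check_grouping(aln, grouping)
  aln$seqs[grouping$population == population, , drop = FALSE]
}
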