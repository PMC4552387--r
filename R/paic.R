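# Classification of rooted, geographically labelled trees against the
# hierarchical island-vicariance hypotheses:
#   H0 -- strict inter-island (PAIC) vicariance: each island complex's tips
#         form a clade with no internal region structure;
#   H1 -- separate colonizations: an island complex's tips are not
#         monophyletic and its region clades are unrelated (not sisters);
#   H2 -- within-island differentiation: an island complex is monophyletic
#         but internally split into monophyletic sister region clades;
#   other -- anything matching none of the above.

#' Test whether a tip set is monophyletic
#'
#' TRUE iff some clade of the rooted tree contains exactly `tips`.
#'
#' @param tree an `ape::phylo` tree (rooted).
#' @param tips character vector of tip labels.
#' @return logical.
#' @export
is_monophyletic <- function(tree, tips) {
  unknown <- setdiff(tips, tree$tip.label)
  if (length(unknown)) stop("unknown tips: ", paste(unknown, collapse = ", "),
                            call. = FALSE)
  if (length(tips) == 0) stop("empty tip set", call. = FALSE)
  ape::is.monophyletic(tree, tips)
}

# Are two monophyletic tip sets sister clades? True iff their union's MRCA
# splits exactly into the two sets.
are_sisters <- function(tree, tips_a, tips_b) {
  u <- c(tips_a, tips_b)
  if (!ape::is.monophyletic(tree, u)) return(FALSE)
  ape::is.monophyletic(tree, tips_a) && ape::is.monophyletic(tree, tips_b)
}

#' Classify a labelled tree against the hierarchical vicariance hypotheses
#'
#' Tips are mapped to regions and regions to island complexes (PAICs)
#' through the metadata; tips labelled with an `outgroup` PAIC are pruned
#' before classification. Requires at least two PAICs among the remaining
#' tips. A root polytomy mixing PAICs is reported as `other` with a note.
#'
#' @param tree a rooted `ape::phylo` tree (e.g. from [ape::read.tree()]).
#' @param labels data frame with columns `tip` (or `sample_id`), `region`,
#'   `paic`.
#' @return list with `hypothesis` (`"H0"`, `"H1"`, `"H2"` or `"other"`),
#'   per-PAIC detail (`monophyletic`, regions and their monophyly), and a
#'   `note`.
#' @export
classify_paic_pattern <- function(tree, labels) {
  if (!is.null(labels$sample_id) && is.null(labels$tip)) labels$tip <- labels$sample_id
  need <- c("tip", "region", "paic")
  miss <- setdiff(need, names(labels))
  if (length(miss)) stop("labels missing columns: ", paste(miss, collapse = ", "),
                         call. = FALSE)
  unknown <- setdiff(tree$tip.label, labels$tip)
  if (length(unknown)) stop("unlabelled tips: ", paste(unknown, collapse = ", "),
                            call. = FALSE)
  labels <- labels[match(tree$tip.label, labels$tip), ]
  og <- labels$tip[tolower(labels$paic) %in% c("outgroup", "og")]
  if (length(og)) {
    tree <- ape::drop.tip(tree, og)
    labels <- labels[!(labels$tip %in% og), ]
  }
  paics <- unique(labels$paic)
  if (length(paics) < 2) stop("classification requires >= 2 island complexes",
                              call. = FALSE)

  note <- ""
  # a root polytomy whose branches interleave the complexes is unresolvable
  n <- length(tree$tip.label)
  root <- n + 1L
  root_children <- tree$edge[tree$edge[, 1] == root, 2]
  if (length(root_children) > 2) {
    child_sets <- lapply(root_children, function(ch) {
      tips <- if (ch <= n) tree$tip.label[ch] else
        ape::extract.clade(tree, ch)$tip.label
      unique(labels$paic[match(tips, labels$tip)])
    })
    per_paic <- vapply(paics, function(p)
      sum(vapply(child_sets, function(s) p %in% s, TRUE)), integer(1))
    if (sum(per_paic >= 2) >= 2) note <- "root polytomy across island complexes"
  }

  detail <- lapply(paics, function(p) {
    tips_p <- labels$tip[labels$paic == p]
    regions <- unique(labels$region[labels$paic == p])
    reg_info <- lapply(regions, function(r) {
      tips_r <- labels$tip[labels$region == r & labels$paic == p]
      list(region = r, n = length(tips_r),
           monophyletic = length(tips_r) == length(tree$tip.label) ||
             is_monophyletic(tree, tips_r))
    })
    list(paic = p, n = length(tips_p),
         monophyletic = length(tips_p) == length(tree$tip.label) ||
           is_monophyletic(tree, tips_p),
         regions = reg_info)
  })
  names(detail) <- paics

  paic_mono <- vapply(detail, `[[`, TRUE, "monophyletic")
  split_paic <- vapply(detail, function(d) {
    length(d$regions) >= 2 && all(vapply(d$regions, `[[`, TRUE, "monophyletic"))
  }, TRUE)

  if (nzchar(note)) {
    hypothesis <- "other"
  } else if (all(paic_mono)) {
    hypothesis <- if (any(paic_mono & split_paic)) "H2" else "H0"
    if (hypothesis == "H0" &&
        any(vapply(detail, function(d) length(d$regions) >= 2 &&
                     !all(vapply(d$regions, `[[`, TRUE, "monophyletic")), TRUE))) {
      note <- "region structure within a complex is not cladistic"
    }
  } else {
    bad <- names(paic_mono)[!paic_mono]
    regions_clean <- vapply(bad, function(p) {
      all(vapply(detail[[p]]$regions, `[[`, TRUE, "monophyletic")) &&
        length(detail[[p]]$regions) >= 2
    }, TRUE)
    hypothesis <- if (all(regions_clean)) "H1" else "other"
  }
  list(hypothesis = hypothesis, detail = detail, note = note)
}

#' Write a hypothesis-classification report as JSON
#'
#' @param classification result of [classify_paic_pattern()].
#' @param path output file.
#' @export
write_classification <- function(classification, path) {
  jsonlite::write_json(classification, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
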