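#' Classify OTUs as core, group-specific, or sample-specific
#'
#' Occurrence-pattern classification over a group x habitat design. An OTU
#' is "present" in a cell when it is detected (count > 0) in at least
#' `min_samples` samples of that cell. Detected OTUs are partitioned as:
#'
#' * **core** — present in every habitat of every group (all cells);
#' * **sample_specific** — occurring in a strict subset of the habitats
#'   (one or two of three), regardless of group; this takes precedence
#'   over the group rule, so an OTU missing a habitat everywhere is
#'   sample-specific even when restricted to one group;
#' * **group_specific** — everything else that spans all habitats overall
#'   but not all group x habitat cells (shared by water/biofloc/gut in
#'   some but not all groups).
#'
#' @param counts OTU table (samples x OTUs).
#' @param metadata data.frame with `sample_id`, `group`, `habitat` covering
#'   every sample; every group must contain every habitat.
#' @param min_samples Detection rule: minimum samples per cell with count
#'   > 0 for presence (default 1, the permissive reading of "occurring").
#' @return List with `class` (named character over detected OTUs) and
#'   `occurrence` (logical matrix, cells x OTUs, cell names `group.habitat`).
#' @export
classify_otus <- function(counts, metadata, min_samples = 1) {
  validate_otu_table(counts)
  md <- metadata[match(rownames(counts), metadata$sample_id), ]
  if (anyNA(md$group)) stop("metadata missing for some samples")
  groups <- unique(md$group)
  habitats <- unique(md$habitat)
  cells <- expand.grid(group = groups, habitat = habitats, stringsAsFactors = FALSE)
  occ <- matrix(FALSE, nrow(cells), ncol(counts),
                dimnames = list(paste(cells$group, cells$habitat, sep = "."),
                                colnames(counts)))
  for (k in seq_len(nrow(cells))) {
    idx <- md$group == cells$group[k] & md$habitat == cells$habitat[k]
    if (!any(idx)) stop("empty cell: ", cells$group[k], " x ", cells$habitat[k])
    occ[k, ] <- colSums(counts[idx, , drop = FALSE] > 0) >= min_samples
  }
  detected <- colnames(counts)[colSums(counts) > 0 & colSums(occ) > 0]
  hab_support <- vapply(detected, function(o) {
    length(unique(cells$habitat[occ[, o]]))
  }, integer(1))
  cls <- ifelse(hab_support < length(habitats), "sample_specific",
                ifelse(colSums(occ[, detected, drop = FALSE]) == nrow(cells),
                       "core", "group_specific"))
  names(cls) <- detected
  list(class = cls, occurrence = occ)
}

#' Venn region counts over OTU sets
#'
#' Exact set algebra over k sets of detected OTUs: returns the size of each
#' of the `2^k - 1` exclusive regions, named by the member sets joined with
#' `&`.
#'
#' @param sets Named list of character vectors (>= 2 sets).
#' @return Named integer vector of exclusive region sizes.
#' @export
venn_regions <- function(sets) {
  k <- length(sets)
  if (k < 2) stop("need at least 2 sets")
  if (is.null(names(sets))) names(sets) <- LETTERS[seq_len(k)]
  universe <- unique(unlist(sets))
  member <- vapply(sets, function(s) universe %in% s, logical(length(universe)))
  if (length(universe) == 0) member <- matrix(logical(0), 0, k, dimnames = list(NULL, names(sets)))
  combos <- expand.grid(rep(list(c(FALSE, TRUE)), k))[-1, , drop = FALSE]
  out <- apply(combos, 1, function(inc) {
    sum(apply(member, 1, function(row) all(row == inc)))
  })
  names(out) <- apply(combos, 1, function(inc) paste(names(sets)[as.logical(inc)], collapse = "&"))
  out
}

#' Levins' niche breadth per OTU
#'
#' For OTU j with share `P_ij` of its summed abundance found in sample i,
#' `B_j = 1 / sum_i P_ij^2` — the inverse Simpson concentration of the
#' OTU's distribution over samples, ranging from 1 (one sample) to the
#' number of samples (perfectly even). Computed over the pooled sample set;
#' pass `groups` to compute it within sample groups instead.
#'
#' @param relabund Relative-abundance (or count) matrix, samples x OTUs.
#' @param groups Optional grouping; returns a matrix (groups x OTUs).
#' @return Named numeric vector of B (or matrix when grouped); absent OTUs
#'   yield `NA`.
#' @export
niche_breadth <- function(relabund, groups = NULL) {
  m <- as.matrix(relabund)
  if (!is.null(groups)) {
    lv <- unique(as.character(groups))
    out <- t(vapply(lv, function(g) niche_breadth(m[groups == g, , drop = FALSE]),
                    numeric(ncol(m))))
    rownames(out) <- lv
    return(out)
  }
  tot <- colSums(m)
  b <- rep(NA_real_, ncol(m))
  pos <- tot > 0
  p <- sweep(m[, pos, drop = FALSE], 2, tot[pos], "/")
  b[pos] <- 1 / colSums(p^2)
  names(b) <- colnames(m)
  b
}
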