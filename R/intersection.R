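#' Assign the intersection label for one bin's significant base groups
#'
#' A bin significant in base groups sharing a sample type or a sex receives
#' the shared axis as its label; significance in all four groups is "All".
#' Pairs differing in both sex and sample type (the two diagonal pairs) are
#' invalid and yield "none", as does significance in fewer than two groups.
#' When three groups are significant, a complete sample-type pair and a
#' complete sex pair coexist; the priority order (default tissue, then
#' cfDNA, then sex) decides which label wins.
#'
#' @param significant_groups character vector, a subset of [base_groups()]
#' @param priority label priority for three-group patterns; a permutation of
#'   `c("tissue", "cfDNA", "sex")`
#' @return List with `label` (one of Tissue, cfDNA, Male, Female, All,
#'   none) and `contributing_groups` (the base groups behind the label; all
#'   four for All, empty for none).
#' @export
assign_label <- function(significant_groups,
                         priority = c("tissue", "cfDNA", "sex")) {
  S <- unique(as.character(significant_groups))
  if (!all(S %in% base_groups()))
    stop("unknown base group: ", paste(setdiff(S, base_groups()), collapse = ", "))
  stopifnot(setequal(priority, c("tissue", "cfDNA", "sex")))
  if (length(S) == 4)
    return(list(label = "All", contributing_groups = base_groups()))
  if (length(S) <= 1)
    return(list(label = "none", contributing_groups = character()))
  pairs <- list(
    tissue = c("male_tissue", "female_tissue"),
    cfDNA = c("male_cfDNA", "female_cfDNA"),
    male = c("male_tissue", "male_cfDNA"),
    female = c("female_tissue", "female_cfDNA")
  )
  lab <- c(tissue = "Tissue", cfDNA = "cfDNA", male = "Male", female = "Female")
  candidates <- unlist(lapply(priority, function(p)
    if (p == "sex") c("male", "female") else p))
  for (cand in candidates) {
    if (all(pairs[[cand]] %in% S))
      return(list(label = unname(lab[cand]),
                  contributing_groups = pairs[[cand]]))
  }
  list(label = "none", contributing_groups = character())  # diagonal pair
}

#' Label every bin from the four per-group screening tables
#'
#' @param results named list of four [screen_bins()] tables (names =
#'   [base_groups()]) over an identical bin universe
#' @param priority passed to [assign_label()]
#' @return A `data.table`: `bin_index`, `label`, `contributing_groups`
#'   (comma-joined).
#' @export
label_all_bins <- function(results, priority = c("tissue", "cfDNA", "sex")) {
  stopifnot(is.list(results), setequal(names(results), base_groups()))
  universe <- results[[base_groups()[1]]]$bin_index
  for (g in base_groups())
    if (!identical(results[[g]]$bin_index, universe))
      stop("bin universes differ across base groups")
  sig <- vapply(base_groups(), function(g) results[[g]]$significant,
                logical(length(universe)))
  if (is.null(dim(sig))) sig <- matrix(sig, nrow = 1)
  # 16 possible patterns: precompute the truth table once
  key <- as.integer(sig %*% 2L^(0:3))
  lut <- lapply(0:15, function(k) {
    assign_label(base_groups()[bitwAnd(k, 2L^(0:3)) > 0], priority)
  })
  labels <- vapply(lut, `[[`, character(1), "label")[key + 1L]
  contrib <- vapply(lut, function(z)
    paste(z$contributing_groups, collapse = ","), character(1))[key + 1L]
  out <- data.table(bin_index = universe, label = labels,
                    contributing_groups = contrib)
  counts <- table(factor(out$label,
                         levels = c("Tissue", "cfDNA", "Male", "Female",
                                    "All", "none")))
  message("intersection labels: ",
          paste(names(counts), as.integer(counts), sep = "=", collapse = " "))
  out
}
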