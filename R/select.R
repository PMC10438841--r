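# Exhaustive covariate-set enumeration under per-category caps, and
# minimum-BIC selection with the delta-BIC > 2 distinguishability rule.

#' Candidate-covariate catalog
#'
#' Groups candidate covariates into named categories, each with a maximum
#' (and optionally minimum) number of members a candidate model may draw
#' from it.  A nitrogen-source category would typically set `min_allowed =
#' 1`: a load model without a nitrogen input term is physically
#' meaningless.
#'
#' @param ... named categories; each is a list with `members` (character
#'   vector of covariate names), `max_allowed`, and optional `min_allowed`
#'   (default 0).
#' @return A list of class `"candidate_catalog"`.
#' @export
#' @examples
#' cat2 <- candidate_catalog(
#'   precip  = list(members = c("P_annual", "P_MJJ"), max_allowed = 1),
#'   surplus = list(members = c("ln_Nsurplus"), max_allowed = 1, min_allowed = 1)
#' )
#' length(enumerate_candidates(cat2))
candidate_catalog <- function(...) {
  cats <- list(...)
  if (length(cats) == 1L && is.null(names(cats)) && is.list(cats[[1L]][[1L]]))
    cats <- cats[[1L]]
  if (is.null(names(cats)) || any(names(cats) == ""))
    stop_invalid("all categories must be named")
  cats <- lapply(cats, function(cc) {
    if (is.null(cc$members) || is.null(cc$max_allowed))
      stop_invalid("each category needs 'members' and 'max_allowed'")
    cc$min_allowed <- cc$min_allowed %||% 0L
    if (cc$max_allowed < 0 || cc$max_allowed > length(cc$members))
      stop_invalid("max_allowed must be in [0, category size]")
    if (cc$min_allowed < 0 || cc$min_allowed > cc$max_allowed)
      stop_invalid("min_allowed must be in [0, max_allowed]")
    cc
  })
  structure(cats, class = "candidate_catalog")
}

# All subsets of `members` of size min_allowed..max_allowed, in a fixed
# deterministic order (by size, then lexicographic combination order).
category_choices <- function(cc) {
  out <- list()
  for (k in cc$min_allowed:cc$max_allowed) {
    if (k == 0L) { out[[length(out) + 1L]] <- character(0); next }
    cmb <- utils::combn(cc$members, k, simplify = FALSE)
    out <- c(out, cmb)
  }
  out
}

#' Enumerate candidate covariate sets under category caps
#'
#' Produces every covariate set formed by choosing between the per-category
#' minimum and maximum number of members from each category; the number of
#' sets equals the product over categories of the per-category subset
#' counts.
#'
#' @param catalog a [candidate_catalog()].
#' @param max_sets refuse (with the would-be count) if the enumeration
#'   exceeds this cap.
#' @return A list of character vectors (covariate sets) in deterministic
#'   order.
#' @export
enumerate_candidates <- function(catalog, max_sets = 10000L) {
  stopifnot(inherits(catalog, "candidate_catalog"))
  per_cat <- lapply(catalog, category_choices)
  total <- prod(vapply(per_cat, length, numeric(1)))
  if (total > max_sets)
    stop_invalid("enumeration would produce ", format(total, big.mark = ","),
                 " candidate sets (cap ", max_sets, ")")
  idx <- do.call(expand.grid, c(lapply(per_cat, seq_along),
                                list(KEEP.OUT.ATTRS = FALSE)))
  lapply(seq_len(nrow(idx)), function(i) {
    unlist(lapply(seq_along(per_cat), function(j) per_cat[[j]][[idx[i, j]]]),
           use.names = FALSE)
  })
}

#' Select the minimum-BIC model over a candidate catalog
#'
#' Fits every enumerated covariate set with [nload_gam()] and ranks the
#' candidates by BIC.  Two models are considered distinguishable only when
#' their BIC values differ by more than two; candidates within two of the
#' winner are reported as near-ties.  Candidate fits that fail are logged
#' and excluded rather than aborting the search.
#'
#' @param data catchment-year data frame (must contain `Q_TN`).
#' @param catalog a [candidate_catalog()].
#' @param term_kind either a single kind (`"linear"` or `"smooth"`) applied
#'   to every covariate, or a named character vector giving the kind per
#'   covariate (unnamed covariates default to linear).
#' @param k basis size used for smooth terms.
#' @param max_sets enumeration cap (see [enumerate_candidates()]).
#' @return A list of class `"selection_result"`: `ranking` (data frame with
#'   covariates, edf, BIC, delta BIC), `selected` (the winning fitted
#'   model), `near_ties` (row indices of the ranking within delta BIC <=
#'   2), and `failures`.
#' @export
select_model <- function(data, catalog, term_kind = "linear", k = 10L,
                         max_sets = 10000L) {
  sets <- enumerate_candidates(catalog, max_sets = max_sets)
  kind_of <- function(v) {
    if (length(term_kind) == 1L && is.null(names(term_kind))) return(term_kind)
    if (v %in% names(term_kind)) unname(term_kind[[v]]) else "linear"
  }
  make_terms <- function(set) lapply(set, function(v) {
    kd <- kind_of(v)
    if (identical(kd, "smooth")) term_smooth(v, k) else term_linear(v)
  })
  rows <- vector("list", length(sets))
  fits <- vector("list", length(sets))
  failures <- character(0)
  for (i in seq_along(sets)) {
    set <- sets[[i]]
    fit <- tryCatch(
      suppressWarnings(nload_gam(data, terms = make_terms(set))),
      error = function(e) e)
    if (inherits(fit, "error")) {
      failures <- c(failures, sprintf("{%s}: %s", paste(set, collapse = ","),
                                      conditionMessage(fit)))
      next
    }
    fits[[i]] <- fit
    rows[[i]] <- data.frame(
      set = i, covariates = paste(sort(set), collapse = "+"),
      n_covariates = length(set), edf = fit$edf, bic = fit$bic,
      stringsAsFactors = FALSE)
  }
  ranking <- do.call(rbind, rows)
  if (is.null(ranking)) stop_invalid("all candidate fits failed")
  ord <- order(ranking$bic)
  ranking <- ranking[ord, , drop = FALSE]
  ranking$delta_bic <- ranking$bic - ranking$bic[1L]
  rownames(ranking) <- NULL
  near <- which(ranking$delta_bic <= 2)
  structure(list(
    ranking = ranking,
    selected = fits[[ranking$set[1L]]],
    selected_covariates = strsplit(ranking$covariates[1L], "+", fixed = TRUE)[[1L]],
    near_ties = near[near != 1L],
    failures = failures
  ), class = "selection_result")
}

#' @export
print.selection_result <- function(x, n = 5L, ...) {
  cat("BIC model selection over", nrow(x$ranking), "candidate sets\n")
  cat("selected: {", x$ranking$covariates[1L], "}  BIC =",
      sprintf("%.1f", x$ranking$bic[1L]), "\n")
  if (length(x$near_ties))
    cat("near-ties (delta BIC <= 2):",
        paste(x$ranking$covariates[x$near_ties], collapse = " | "), "\n")
  if (length(x$failures)) cat(length(x$failures), "candidate fits failed\n")
  print(utils::head(x$ranking[, c("covariates", "edf", "bic", "delta_bic")], n),
        row.names = FALSE)
  invisible(x)
}
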