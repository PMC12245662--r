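#' Number of possible non-empty signatures
#'
#' With `n_selected` features there are `2^n_selected - 1` non-empty
#' feature subsets. Computed in exact double arithmetic (exact up to
#' 2^53 - 1, far beyond any realistic selected-feature count).
#'
#' @param n_selected number of selected features (>= 1).
#' @return a single numeric count.
#' @examples
#' count_all_signatures(9)   # 511
#' count_all_signatures(28)  # 268435455
#' @export
count_all_signatures <- function(n_selected) {
  assert_scalar_count(n_selected, "n_selected")
  2^n_selected - 1
}

#' Number of signatures drawn by the planner
#'
#' Three signatures per size over sizes `2 .. n_selected - 1`, i.e.
#' `3 * (n_selected - 2)`. This is the evaluated subset of the
#' `2^n_selected - 1` possible signatures: 21 when 9 features are
#' selected, 78 for 28, 108 for 38.
#'
#' @param n_selected number of selected features (>= 3; below that no size
#'   range exists).
#' @return a single integer.
#' @export
planned_signature_count <- function(n_selected) {
  assert_scalar_count(n_selected, "n_selected", min = 3L)
  3L * (as.integer(n_selected) - 2L)
}

#' Draw the candidate-signature plan
#'
#' For each size `s` in `2 .. Nv' - 1` draws 3 distinct feature subsets
#' uniformly without replacement from the `choose(Nv', s)` possibilities,
#' giving `3 * (Nv' - 2)` signatures in total. Small subset spaces
#' (`choose(Nv', s) <= 10000`) are fully enumerated and sampled exactly;
#' larger ones use rejection sampling of subsets, which is effectively
#' collision-free at these sizes.
#'
#' @param selected_features character vector of Nv' >= 4 distinct feature
#'   ids.
#' @param seed integer seed; the plan is deterministic given it.
#' @return an object of class `SignaturePlan`: list with
#'   `n_selected_features`, `signatures` (named list of feature-id
#'   vectors, ids `sig001`, ...), `sizes`, `seed`.
#' @examples
#' plan <- plan_signatures(paste0("g", 1:9), seed = 1)
#' length(plan$signatures)  # 21
#' table(plan$sizes)        # 3 of each size 2..8
#' @export
plan_signatures <- function(selected_features, seed = 1L) {
  selected_features <- as.character(selected_features)
  if (anyDuplicated(selected_features)) {
    stop("`selected_features` contains duplicates")
  }
  nv <- length(selected_features)
  if (nv < 4L) {
    stop("at least 4 selected features are needed to draw 3 signatures per size")
  }
  set.seed(seed)
  sizes_grid <- 2:(nv - 1L)
  signatures <- list()
  sizes <- integer(0)
  for (s in sizes_grid) {
    total <- choose(nv, s)
    if (total <= 10000) {
      all_subsets <- utils::combn(selected_features, s, simplify = FALSE)
      chosen <- all_subsets[sample.int(length(all_subsets), 3L)]
    } else {
      chosen <- list()
      keys <- character(0)
      while (length(chosen) < 3L) {
        cand <- sort(sample(selected_features, s))
        key <- paste(cand, collapse = "\r")
        if (!key %in% keys) {
          chosen <- c(chosen, list(cand))
          keys <- c(keys, key)
        }
      }
    }
    signatures <- c(signatures, lapply(chosen, sort))
    sizes <- c(sizes, rep(s, 3L))
  }
  names(signatures) <- sprintf("sig%03d", seq_along(signatures))
  structure(list(n_selected_features = nv,
                 selected_features = selected_features,
                 signatures = signatures, sizes = sizes,
                 seed = as.integer(seed)),
            class = "SignaturePlan")
}

#' @export
print.SignaturePlan <- function(x, ...) {
  cat(sprintf("SignaturePlan: %d signatures (3 per size %d..%d) from %d features\n",
              length(x$signatures), min(x$sizes), max(x$sizes),
              x$n_selected_features))
  invisible(x)
}

#' Serialise / restore a signature plan
#'
#' JSON maps signature id to its feature-id list; the TSV form has two
#' columns (signature id, comma-joined feature ids).
#'
#' @param plan a `SignaturePlan`.
#' @param file output/input path.
#' @return `read_signature_plan()` returns a `SignaturePlan`.
#' @export
write_signature_plan <- function(plan, file) {
  obj <- list(n_selected_features = plan$n_selected_features,
              selected_features = plan$selected_features,
              seed = plan$seed, signatures = plan$signatures)
  jsonlite::write_json(obj, file, auto_unbox = TRUE, pretty = TRUE)
  invisible(plan)
}

#' @rdname write_signature_plan
#' @export
read_signature_plan <- function(file) {
  obj <- jsonlite::read_json(file, simplifyVector = FALSE)
  signatures <- lapply(obj$signatures, function(s) unlist(s))
  structure(list(n_selected_features = as.integer(obj$n_selected_features),
                 selected_features = unlist(obj$selected_features),
                 signatures = signatures,
                 sizes = lengths(signatures),
                 seed = as.integer(obj$seed)),
            class = "SignaturePlan")
}

#' @rdname write_signature_plan
#' @export
write_signature_plan_tsv <- function(plan, file) {
  df <- data.frame(signature_id = names(plan$signatures),
                   features = vapply(plan$signatures, paste,
                                     character(1), collapse = ","))
  utils::write.table(df, file, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(plan)
}
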