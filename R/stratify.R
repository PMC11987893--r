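#' Stratification plan for dissection sampling
#'
#' Defines the backfat and weight strata and the required carcass counts per
#' cell for a grading-device dissection test. The default reproduces the
#' CGM test design: fat groups 1-3 bounded at 10 and 18 mm, weight groups
#' A-C bounded at 84.4 and 105.5 kg over the admissible range 60-120 kg,
#' 126 partial-dissection carcasses with marginals 30/66/30 (fat) and
#' 32/62/32 (weight), and a 12-carcass total-dissection subsample in a
#' 1/2/1 pattern per weight row.
#'
#' The printed integer bin labels leave gaps between strata (e.g. fat
#' "0-10" then "11-18"); bins are encoded half-open on the upper edge
#' (group 1 is f2 <= 10, group 2 is 10 < f2 <= 18) so that every positive
#' measurement is classifiable.
#'
#' @param fat_breaks increasing fat-depth cut points (mm) including the
#'   outer bounds; defines `length(fat_breaks) - 1` groups.
#' @param weight_breaks increasing hot-weight cut points (kg); the first
#'   and last are the admissible weight range.
#' @param required_counts matrix (weight group x fat group) of required
#'   partial-dissection carcasses.
#' @param required_subsample matrix of required total-dissection carcasses;
#'   each cell must not exceed the corresponding `required_counts` cell.
#' @return an object of class `stratification_plan`.
#' @export
stratification_plan <- function(fat_breaks = c(0, 10, 18, Inf),
                                weight_breaks = c(60, 84.4, 105.5, 120),
                                required_counts = default_required_counts(),
                                required_subsample = default_required_subsample()) {
  if (is.unsorted(fat_breaks, strictly = TRUE) ||
      is.unsorted(weight_breaks, strictly = TRUE))
    stop("bin breaks must be strictly increasing", call. = FALSE)
  nf <- length(fat_breaks) - 1L
  nw <- length(weight_breaks) - 1L
  required_counts <- as.matrix(required_counts)
  required_subsample <- as.matrix(required_subsample)
  if (!all(dim(required_counts) == c(nw, nf)))
    stop("'required_counts' must be ", nw, " x ", nf, call. = FALSE)
  if (!all(dim(required_subsample) == c(nw, nf)))
    stop("'required_subsample' must be ", nw, " x ", nf, call. = FALSE)
  if (any(required_counts < 0) || any(required_subsample < 0))
    stop("required counts must be non-negative", call. = FALSE)
  if (any(required_subsample > required_counts))
    stop("subsample requirement exceeds sample requirement in some cell",
         call. = FALSE)
  dimnames(required_counts) <- dimnames(required_subsample) <-
    list(weight_group = LETTERS[seq_len(nw)],
         fat_group = as.character(seq_len(nf)))
  structure(list(fat_breaks = fat_breaks,
                 weight_breaks = weight_breaks,
                 required_counts = required_counts,
                 required_subsample = required_subsample),
            class = "stratification_plan")
}

default_required_counts <- function() {
  matrix(c(7, 18, 7,
           16, 30, 16,
           7, 18, 7), nrow = 3, byrow = TRUE)
}

default_required_subsample <- function() {
  matrix(c(1, 2, 1,
           1, 2, 1,
           1, 2, 1), nrow = 3, byrow = TRUE)
}

#' @export
print.stratification_plan <- function(x, ...) {
  cat("Stratification plan:",
      sum(x$required_counts), "carcasses,",
      sum(x$required_subsample), "total-dissection subsample\n")
  cat("Required partial-dissection counts (weight x fat):\n")
  print(x$required_counts)
  cat("Required total-dissection subsample:\n")
  print(x$required_subsample)
  invisible(x)
}

#' Assign backfat groups
#'
#' Maps fat depth F2 to its stratum index; with the default plan, group 1
#' is f2 <= 10 mm, group 2 is 10 < f2 <= 18 mm and group 3 is f2 > 18 mm.
#'
#' @param f2 fat depth(s) in mm, positive.
#' @param plan a [stratification_plan()].
#' @return integer group indices.
#' @export
assign_fat_group <- function(f2, plan = stratification_plan()) {
  if (any(!is.finite(f2)) || any(f2 <= 0))
    stop("'f2' must be positive", call. = FALSE)
  as.integer(cut(f2, breaks = plan$fat_breaks, labels = FALSE,
                 right = TRUE, include.lowest = TRUE))
}

#' Assign weight groups
#'
#' Maps hot carcass weight to its stratum (A, B, C with the default plan:
#' A is w <= 84.4 kg, B is 84.4 < w <= 105.5 kg, C is w > 105.5 kg).
#' Weights outside the plan's admissible range are rejected.
#'
#' @param hot_weight hot carcass weight(s) in kg.
#' @param plan a [stratification_plan()].
#' @return character group labels (`"A"`, `"B"`, ...).
#' @export
assign_weight_group <- function(hot_weight, plan = stratification_plan()) {
  lo <- plan$weight_breaks[1]
  hi <- plan$weight_breaks[length(plan$weight_breaks)]
  bad <- !is.finite(hot_weight) | hot_weight < lo | hot_weight > hi
  if (any(bad))
    stop(sprintf("hot carcass weight outside the plan range [%g, %g] kg: %s",
                 lo, hi, paste(utils::head(hot_weight[bad], 5),
                               collapse = ", ")), call. = FALSE)
  idx <- as.integer(cut(hot_weight, breaks = plan$weight_breaks,
                        labels = FALSE, right = TRUE,
                        include.lowest = TRUE))
  LETTERS[idx]
}

#' Draw a stratified dissection sample
#'
#' For each (weight group, fat group) cell, draws uniformly at random
#' without replacement up to the required number of carcasses; cells with
#' too few candidates are recorded as shortfalls rather than raised as
#' errors, mirroring field practice where small deficits are tolerated.
#' A total-dissection subsample is then drawn from the selected carcasses
#' per the plan's subsample matrix. Deterministic for a fixed seed.
#'
#' @param population a carcass data frame with `id`, `hot_weight_kg`,
#'   `f2_mm` columns (e.g. from [generate_population()]). Carcasses outside
#'   the plan's weight range are excluded from candidacy (they cannot be
#'   assigned a stratum).
#' @param plan a [stratification_plan()].
#' @param seed integer seed for the random draws.
#' @return an object of class `selection_result` with elements
#'   `selected` (the sampled rows plus `fat_group`, `weight_group`,
#'   `in_subsample` columns), `achieved_counts`, `achieved_subsample`,
#'   and `shortfalls` (data frame of cells with deficits).
#' @export
select_sample <- function(population, plan = stratification_plan(),
                          seed = NULL) {
  if (NROW(population) == 0L)
    stop("'population' is empty", call. = FALSE)
  if (anyDuplicated(population$id))
    stop("duplicate carcass ids in the population", call. = FALSE)

  lo <- plan$weight_breaks[1]
  hi <- plan$weight_breaks[length(plan$weight_breaks)]
  eligible <- population[population$hot_weight_kg >= lo &
                           population$hot_weight_kg <= hi, , drop = FALSE]
  fat_g <- assign_fat_group(eligible$f2_mm, plan)
  wt_g <- assign_weight_group(eligible$hot_weight_kg, plan)

  req <- plan$required_counts
  req_sub <- plan$required_subsample
  nw <- nrow(req); nf <- ncol(req)
  achieved <- req * 0L
  achieved_sub <- req_sub * 0L
  picked <- list()

  with_seed(seed, {
    for (i in seq_len(nw)) {
      for (j in seq_len(nf)) {
        in_cell <- which(wt_g == LETTERS[i] & fat_g == j)
        k <- min(req[i, j], length(in_cell))
        take <- in_cell[sample.int(length(in_cell), k)]
        ks <- min(req_sub[i, j], k)
        sub_take <- take[sample.int(length(take), ks)]
        achieved[i, j] <- k
        achieved_sub[i, j] <- ks
        if (k > 0) {
          rows <- eligible[take, , drop = FALSE]
          rows$fat_group <- j
          rows$weight_group <- LETTERS[i]
          rows$in_subsample <- rows$id %in% eligible$id[sub_take]
          picked[[length(picked) + 1L]] <- rows
        }
      }
    }
    selected <- if (length(picked)) do.call(rbind, picked) else
      cbind(eligible[0, , drop = FALSE], fat_group = integer(0),
            weight_group = character(0), in_subsample = logical(0))
    rownames(selected) <- NULL
    deficits <- req - achieved
    idx <- which(deficits > 0, arr.ind = TRUE)
    shortfalls <- data.frame(
      weight_group = rownames(req)[idx[, 1]],
      fat_group = as.integer(colnames(req)[idx[, 2]]),
      deficit = deficits[idx],
      stringsAsFactors = FALSE
    )
    structure(list(selected = selected,
                   achieved_counts = achieved,
                   achieved_subsample = achieved_sub,
                   shortfalls = shortfalls,
                   plan = plan),
              class = "selection_result")
  })
}

#' @export
print.selection_result <- function(x, ...) {
  cat("Stratified selection:", nrow(x$selected), "carcasses selected (",
      sum(x$selected$in_subsample), "in total-dissection subsample)\n")
  print(x$achieved_counts)
  if (nrow(x$shortfalls)) {
    cat("Shortfalls:\n")
    print(x$shortfalls)
  } else cat("No shortfalls; plan achieved exactly.\n")
  invisible(x)
}

#' Validate a stratification plan against design conventions
#'
#' Checks that the fat-group and weight-group marginal totals each follow
#' the conventional 1:2:1 allocation (within a relative tolerance) and
#' that the total-dissection subsample is close to 10% of the sample.
#'
#' @param plan a [stratification_plan()].
#' @param ratio target allocation across groups (recycled to the number of
#'   groups); default `c(1, 2, 1)`.
#' @param ratio_tol maximum relative deviation of each marginal share from
#'   its target share.
#' @param subsample_share target subsample fraction of the full sample.
#' @param share_tol absolute tolerance on the subsample fraction.
#' @return a list (class `plan_validation`) with logical `ratio_fat_ok`,
#'   `ratio_weight_ok`, `subsample_ok`, `ok`, plus the measured shares.
#' @export
validate_plan <- function(plan, ratio = c(1, 2, 1), ratio_tol = 0.15,
                          subsample_share = 0.10, share_tol = 0.03) {
  target <- ratio / sum(ratio)
  fat_tot <- colSums(plan$required_counts)
  wt_tot <- rowSums(plan$required_counts)
  fat_share <- fat_tot / sum(fat_tot)
  wt_share <- wt_tot / sum(wt_tot)
  rel_dev <- function(share) max(abs(share - target) / target)
  sub_frac <- sum(plan$required_subsample) / sum(plan$required_counts)
  out <- list(
    ratio_fat_ok = length(fat_share) == length(target) &&
      rel_dev(fat_share) <= ratio_tol,
    ratio_weight_ok = length(wt_share) == length(target) &&
      rel_dev(wt_share) <= ratio_tol,
    subsample_ok = abs(sub_frac - subsample_share) <= share_tol,
    fat_share = fat_share, weight_share = wt_share,
    subsample_fraction = sub_frac
  )
  out$ok <- out$ratio_fat_ok && out$ratio_weight_ok && out$subsample_ok
  structure(out, class = "plan_validation")
}

#' @export
print.plan_validation <- function(x, ...) {
  flag <- function(b) if (b) "OK" else "FAIL"
  cat(sprintf("fat-group 1:2:1 allocation:    %s (%s)\n",
              flag(x$ratio_fat_ok),
              paste(round(x$fat_share, 3), collapse = "/")))
  cat(sprintf("weight-group 1:2:1 allocation: %s (%s)\n",
              flag(x$ratio_weight_ok),
              paste(round(x$weight_share, 3), collapse = "/")))
  cat(sprintf("subsample ~10%% of sample:      %s (%.1f%%)\n",
              flag(x$subsample_ok), 100 * x$subsample_fraction))
  invisible(x)
}
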