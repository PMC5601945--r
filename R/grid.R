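#' Model-grid constants
#'
#' The p-value, MAF-cutoff and r-squared grids that define the three
#' model families: 5 MAF cutoffs x 26 p-thresholds = 130 wGRS models on
#' all SNPs, 8 r-squared thresholds x 26 = 208 wGRS models on
#' LD-independent sets, and (1 + 8) x 26 = 234 PRS models.
#'
#' @format Numeric vectors.
#' @name grid_constants
NULL

#' @rdname grid_constants
#' @export
P_GRID <- c(1, 0.6, 0.5, 0.4, 0.3, 0.2, 0.19, 0.18, 0.17, 0.16, 0.15,
            0.14, 0.13, 0.12, 0.11, 0.1, 0.09, 0.08, 0.07, 0.06, 0.05,
            0.04, 0.03, 0.02, 0.01, 0.005)

#' @rdname grid_constants
#' @export
MAF_GRID <- c(0.5, 0.4, 0.3, 0.2, 0.1)

#' @rdname grid_constants
#' @export
LD_R2_GRID <- c(0.8, 0.7, 0.6, 0.5, 0.4, 0.3, 0.2, 0.1)

#' Train the per-SNP components of a risk model on one cohort
#'
#' Computes, on the training cohort only: the minor-allele assignment,
#' the per-SNP logistic weights, and the family of LD-pruned SNP sets
#' (one per r-squared threshold, sharing a single windowed-r2 pass).
#'
#' @param cohort The training [geno_cohort()] (QC already applied).
#' @param r2_thresholds r-squared thresholds to prune at (default
#'   [LD_R2_GRID]).
#' @param window_bp Pruning window in base pairs (default 200000).
#' @param ma_sample Passed to [assign_minor_alleles()].
#' @param prune Logical; set `FALSE` to skip the LD pass when only
#'   total-SNP models are needed.
#' @return An object of class `ma_trained`: list with `ma`, `weights`,
#'   `pruned` (named list of kept snp_id vectors), `window_bp`,
#'   `n_subjects`.
#' @export
train_risk_model <- function(cohort, r2_thresholds = LD_R2_GRID,
                             window_bp = 200000,
                             ma_sample = c("controls", "all"),
                             prune = TRUE) {
  ma <- assign_minor_alleles(cohort, sample = match.arg(ma_sample))
  weights <- fit_snp_weights(cohort, ma)
  pruned <- list()
  if (prune && length(r2_thresholds)) {
    pairs <- ld_windowed_r2(cohort, window_bp)
    maf_all <- {
      f1 <- colMeans(cohort$dosage, na.rm = TRUE) / 2
      pmin(f1, 1 - f1)
    }
    pruned <- lapply(r2_thresholds, function(t) {
      ld_prune(cohort, t, window_bp, maf = maf_all, pairs = pairs)
    })
    names(pruned) <- format_r2(r2_thresholds)
  }
  structure(list(ma = ma, weights = weights, pruned = pruned,
                 window_bp = window_bp, n_subjects = nrow(cohort$dosage)),
            class = "ma_trained")
}

format_r2 <- function(x) format(x, trim = TRUE, drop0trailing = TRUE)

#' Build a grid of prediction-model specifications
#'
#' Resolves every grid cell of a model family to its training-cohort SNP
#' list: SNPs with usable weights passing the family's frequency or LD
#' filter *and* a per-SNP association p-value below the cell's threshold.
#' wGRS families: `"total_by_maf"` (5 MAF cutoffs x 26 p-thresholds =
#' 130 cells) or `"ld_independent"` (8 r-squared thresholds x 26 =
#' 208 cells).  The PRS family combines one total-SNP
#' group (minor alleles only, i.e. MAF < 0.5) with the 8 LD groups for
#' (1 + 8) x 26 = 234 cells.  Cells whose SNP list is empty are retained
#' but marked unevaluable.
#'
#' @param trained A [train_risk_model()] result.
#' @param score_type `"wgrs"` or `"prs"`.
#' @param filter_kind For wGRS, `"total_by_maf"` or `"ld_independent"`;
#'   ignored for PRS (its family is fixed).
#' @param p_grid,maf_grid Threshold grids (defaults [P_GRID], [MAF_GRID]).
#' @return A tibble with one row per model: `model_id`, `score_type`,
#'   `filter_kind`, `maf_cutoff`, `r2_threshold`, `p_threshold`,
#'   `n_snps`, `evaluable`, `snp_ids` (list-column).
#' @export
build_model_grid <- function(trained, score_type = c("wgrs", "prs"),
                             filter_kind = c("total_by_maf", "ld_independent"),
                             p_grid = P_GRID, maf_grid = MAF_GRID) {
  stopifnot(inherits(trained, "ma_trained"))
  score_type <- match.arg(score_type)
  w <- trained$weights
  base_ok <- w$usable & !is.na(w$p_value)
  groups <- list()
  add_group <- function(label, kind, maf_cutoff, r2, ids) {
    groups[[label]] <<- list(kind = kind, maf_cutoff = maf_cutoff,
                             r2 = r2, ids = ids)
  }
  if (score_type == "wgrs") {
    filter_kind <- match.arg(filter_kind)
    if (filter_kind == "total_by_maf") {
      for (c_ in maf_grid) {
        add_group(paste0("maf<", format_r2(c_)), "total_by_maf", c_, NA_real_,
                  w$snp_id[base_ok & !is.na(w$maf) & w$maf < c_])
      }
    } else {
      for (t in names(trained$pruned)) {
        add_group(paste0("r2<", t), "ld_independent", NA_real_, as.numeric(t),
                  intersect(trained$pruned[[t]], w$snp_id[base_ok]))
      }
      if (!length(trained$pruned)) {
        abort("`trained` has no pruned SNP sets; rerun train_risk_model(prune = TRUE)")
      }
    }
  } else {
    # PRS: one total group (all minor alleles, MAF < 0.5) plus the LD groups
    add_group("total", "total_by_maf", 0.5, NA_real_, w$snp_id[base_ok])
    for (t in names(trained$pruned)) {
      add_group(paste0("r2<", t), "ld_independent", NA_real_, as.numeric(t),
                intersect(trained$pruned[[t]], w$snp_id[base_ok]))
    }
  }
  pmap_rows <- purrr::map(names(groups), function(g) {
    gr <- groups[[g]]
    pv <- w$p_value[match(gr$ids, w$snp_id)]
    purrr::map(p_grid, function(p) {
      ids <- gr$ids[pv < p]
      tibble(score_type = score_type, filter_kind = gr$kind,
             maf_cutoff = gr$maf_cutoff, r2_threshold = gr$r2,
             p_threshold = p, n_snps = length(ids),
             evaluable = length(ids) > 0, snp_ids = list(ids))
    })
  })
  out <- dplyr::bind_rows(purrr::flatten(pmap_rows))
  out <- dplyr::mutate(out, model_id = sprintf(
    "%s_%s_p%s", score_type,
    ifelse(.data$filter_kind == "total_by_maf",
           paste0("maf", format_r2(.data$maf_cutoff)),
           paste0("r2-", format_r2(.data$r2_threshold))),
    format_r2(.data$p_threshold)
  ), .before = 1)
  out
}

# Score a validation cohort for every cell of a grid in one pass per
# filter group: for each group the per-SNP weights are masked by the 26
# p-thresholds into a SNPs x cells matrix and applied by a single
# matrix product (and likewise for the per-subject SNP-use counts).
score_grid <- function(valid, trained, grid) {
  D_all <- minor_dosage(valid, trained$ma)
  w <- trained$weights
  n <- nrow(D_all)
  scores <- matrix(NA_real_, n, nrow(grid))
  n_used <- matrix(0L, n, nrow(grid))
  key <- paste(grid$score_type, grid$filter_kind,
               grid$maf_cutoff, grid$r2_threshold)
  for (g in unique(key)) {
    cells <- which(key == g)
    base_ids <- unique(unlist(grid$snp_ids[cells]))
    if (!length(base_ids)) next
    jc <- match(base_ids, valid$snps$snp_id)
    jw <- match(base_ids, w$snp_id)
    D <- D_all[, jc, drop = FALSE]
    storage.mode(D) <- "double"
    Mi <- !is.na(D)
    D[!Mi] <- 0
    type <- grid$score_type[cells[1]]
    per_snp <- if (type == "wgrs") w$beta[jw] else log10(w$odds_ratio[jw])
    G <- if (type == "wgrs") D / 2 else D
    B <- matrix(0, length(base_ids), length(cells))
    Ind <- matrix(0, length(base_ids), length(cells))
    for (k in seq_along(cells)) {
      inset <- base_ids %in% grid$snp_ids[[cells[k]]]
      B[inset, k] <- per_snp[inset]
      Ind[inset, k] <- 1
    }
    scores[, cells] <- G %*% B
    n_used[, cells] <- matrix(as.integer(Mi %*% Ind), n)
  }
  list(scores = scores, n_used = n_used)
}

#' Evaluate every model of a grid on a scored cohort
#'
#' Scores the evaluation cohort with the training-cohort weights for
#' each grid cell and computes AUC (DeLong 95% CI), TPR at 100%
#' specificity (Clopper-Pearson 95% CI) and the Nagelkerke variance
#' explained over the SNP-count covariate.
#'
#' @param valid The cohort to evaluate on (already harmonized to the
#'   training SNP universe).
#' @param trained A [train_risk_model()] result from the training cohort.
#' @param grid A [build_model_grid()] tibble (possibly several families
#'   row-bound together).
#' @param nagelkerke Logical; skip the (glm-based) Nagelkerke column when
#'   `FALSE`.
#' @return The grid tibble with metric columns appended (`auc`,
#'   `auc_lo`, `auc_hi`, `tpr`, `tpr_lo`, `tpr_hi`, `delta_r2`), class
#'   `ma_grid`.
#' @export
evaluate_grid <- function(valid, trained, grid, nagelkerke = TRUE) {
  # allow re-evaluation of an already-evaluated grid (e.g. permutation runs)
  grid <- dplyr::select(grid, -dplyr::any_of(c(
    "auc", "auc_lo", "auc_hi", "tpr", "tpr_lo", "tpr_hi", "delta_r2"
  )))
  sc <- score_grid(valid, trained, grid)
  labels <- valid$subjects$status
  mets <- purrr::map(seq_len(nrow(grid)), function(k) {
    if (!grid$evaluable[k]) {
      return(tibble(auc = NA_real_, auc_lo = NA_real_, auc_hi = NA_real_,
                    tpr = NA_real_, tpr_lo = NA_real_, tpr_hi = NA_real_,
                    delta_r2 = NA_real_))
    }
    s <- sc$scores[, k]
    a <- score_auc(s, labels)
    t <- tpr_full_specificity(s, labels)
    d <- if (nagelkerke) {
      nagelkerke_delta_r2(s, sc$n_used[, k], labels)$delta_r2
    } else NA_real_
    tibble(auc = a$auc, auc_lo = a$ci_lo, auc_hi = a$ci_hi,
           tpr = t$tpr, tpr_lo = t$ci_lo, tpr_hi = t$ci_hi, delta_r2 = d)
  })
  out <- dplyr::bind_cols(grid, dplyr::bind_rows(mets))
  attr(out, "n_cases") <- sum(labels == "case")
  attr(out, "n_controls") <- sum(labels == "control")
  class(out) <- c("ma_grid", class(out))
  out
}

#' Select the best (optimal) prediction model from an evaluated grid
#'
#' Applies a performance screen, then ranks the surviving models by AUC,
#' breaking ties by TPR, then Nagelkerke delta-R2, then the smaller SNP
#' count, then the lexicographic model id (fully deterministic).  The
#' default screen keeps models with AUC > 0.57 and TPR >= 2% in
#' total-SNP families or TPR >= 2.78% in LD-independent families; pass
#' `screen = NULL` to rank all evaluable models.
#'
#' @param grid_result An [evaluate_grid()] tibble.
#' @param screen `NULL`, or a list with elements `total` and `ld`, each
#'   `c(auc = , tpr = )`.
#' @return The selected one-row tibble, or a zero-row tibble (with a
#'   message) when nothing passes the screen.
#' @export
select_best_model <- function(grid_result, screen = default_screen()) {
  g <- dplyr::filter(grid_result, .data$evaluable, !is.na(.data$auc))
  if (!is.null(screen)) {
    keep_total <- g$filter_kind == "total_by_maf" &
      g$auc > screen$total[["auc"]] & g$tpr >= screen$total[["tpr"]]
    keep_ld <- g$filter_kind == "ld_independent" &
      g$auc > screen$ld[["auc"]] & g$tpr >= screen$ld[["tpr"]]
    g <- g[keep_total | keep_ld, , drop = FALSE]
  }
  if (!nrow(g)) {
    message("no model passes the performance screen")
    return(g)
  }
  d2 <- ifelse(is.na(g$delta_r2), -Inf, g$delta_r2)
  o <- order(-g$auc, -g$tpr, -d2, g$n_snps, g$model_id)
  g[o[1], , drop = FALSE]
}

#' @rdname select_best_model
#' @export
default_screen <- function() {
  list(total = c(auc = 0.57, tpr = 0.02), ld = c(auc = 0.57, tpr = 0.0278))
}

#' Write an evaluated model grid as a tab-separated table
#'
#' One row per model with its filter, thresholds, SNP count and metrics
#' (the `snp_ids` list-column is dropped).
#'
#' @param grid_result An [evaluate_grid()] tibble.
#' @param path Output path.
#' @export
write_grid <- function(grid_result, path) {
  readr::write_tsv(dplyr::select(as_tibble(grid_result), -dplyr::any_of("snp_ids")),
                   path, progress = FALSE)
  invisible(path)
}
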