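COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

#' Harmonize two cohorts to a shared SNP universe
#'
#' Intersects the two cohorts on `snp_id` and reconciles the counted
#' allele of each shared SNP: a swapped allele order flips the validation
#' dosages, a strand flip is resolved through base complements, and SNPs
#' whose alleles cannot be reconciled are dropped.  Palindromic (A/T or
#' C/G) SNPs whose allele order disagrees are ambiguous under strand
#' uncertainty and are dropped too.  Overlapping subject ids are a hard
#' error: training and validation must be disjoint.
#'
#' @param train,valid Two [geno_cohort()]s.
#' @return A list with the harmonized `train` and `valid` cohorts (same
#'   SNPs, same order, same counted alleles) and a `log` tibble of
#'   dropped/flipped SNPs.
#' @export
harmonize_cohorts <- function(train, valid) {
  overlap <- intersect(train$subjects$subject_id, valid$subjects$subject_id)
  if (length(overlap)) {
    abort(sprintf("cohorts share %d subject id(s); train/validation must be disjoint",
                  length(overlap)))
  }
  shared <- intersect(train$snps$snp_id, valid$snps$snp_id)
  it <- match(shared, train$snps$snp_id)
  iv <- match(shared, valid$snps$snp_id)
  a1 <- train$snps$a1[it]; a2 <- train$snps$a2[it]
  b1 <- valid$snps$a1[iv]; b2 <- valid$snps$a2[iv]
  palindromic <- COMPLEMENT[a1] == a2
  same <- b1 == a1 & b2 == a2
  swap <- b1 == a2 & b2 == a1
  strand <- b1 == unname(COMPLEMENT[a1]) & b2 == unname(COMPLEMENT[a2])
  strand_swap <- b1 == unname(COMPLEMENT[a2]) & b2 == unname(COMPLEMENT[a1])
  action <- dplyr::case_when(
    same ~ "keep",
    palindromic ~ "drop_ambiguous",     # any disagreement is unresolvable
    swap ~ "flip",
    strand ~ "keep_strand",
    strand_swap ~ "flip_strand",
    TRUE ~ "drop_mismatch"
  )
  log <- tibble(snp_id = shared, action = action)
  keep <- !startsWith(action, "drop")
  flip <- action %in% c("flip", "flip_strand")
  if (sum(!keep)) {
    warn(sprintf("dropping %d shared SNP(s) with irreconcilable alleles",
                 sum(!keep)))
  }
  tr <- subset_cohort(train, snps = it[keep])
  va <- subset_cohort(valid, snps = iv[keep])
  fl <- flip[keep]
  if (any(fl)) {
    va$dosage[, fl] <- 2L - va$dosage[, fl, drop = FALSE]
  }
  # validation carries the training allele labels after reconciliation
  va$snps$a1 <- tr$snps$a1
  va$snps$a2 <- tr$snps$a2
  list(train = tr, valid = va, log = log)
}

#' External cross-validation of the model grids
#'
#' The full two-cohort design: harmonizes the cohorts, trains every
#' per-SNP component (minor-allele status, logistic weights, LD-pruned
#' sets) on the training cohort only, builds the requested model
#' families, scores the validation subjects with training weights and
#' evaluates each model on the validation labels.  No information flows
#' from validation labels into any weight, assignment or SNP list.
#'
#' @param train,valid Training and validation [geno_cohort()]s (QC
#'   applied; disjoint subjects).
#' @param families Character subset of
#'   `c("wgrs_total", "wgrs_ld", "prs")`; default all three
#'   (130 + 208 + 234 models).
#' @param window_bp LD-pruning window (default 200000).
#' @param nagelkerke Passed to [evaluate_grid()].
#' @return An [evaluate_grid()] tibble (class `ma_grid`) covering all
#'   requested families, with the harmonization log and the trained
#'   components attached as attributes `harmonization` and `trained`.
#' @export
external_cv <- function(train, valid,
                        families = c("wgrs_total", "wgrs_ld", "prs"),
                        window_bp = 200000, nagelkerke = TRUE) {
  families <- match.arg(families, several.ok = TRUE)
  h <- harmonize_cohorts(train, valid)
  need_prune <- any(families %in% c("wgrs_ld", "prs"))
  trained <- train_risk_model(h$train, window_bp = window_bp,
                              prune = need_prune)
  grids <- list()
  if ("wgrs_total" %in% families) {
    grids$wgrs_total <- build_model_grid(trained, "wgrs", "total_by_maf")
  }
  if ("wgrs_ld" %in% families) {
    grids$wgrs_ld <- build_model_grid(trained, "wgrs", "ld_independent")
  }
  if ("prs" %in% families) {
    grids$prs <- build_model_grid(trained, "prs")
  }
  grid <- dplyr::bind_rows(grids)
  out <- evaluate_grid(h$valid, trained, grid, nagelkerke = nagelkerke)
  attr(out, "harmonization") <- h$log
  attr(out, "trained") <- trained
  attr(out, "provenance") <- list(training_n = nrow(h$train$dosage),
                                  validation_n = nrow(h$valid$dosage))
  out
}

#' Partition subjects into cross-validation folds
#'
#' Seeded random shuffle followed by a near-equal split: with
#' `n = q * k + r`, the first `r` folds get `q + 1` subjects and the
#' rest `q` (sizes differ by at most 1; 2154 subjects in 10 folds give
#' four folds of 216 and six of 215).  If a fold misses a class the
#' partition is redrawn, up to 100 attempts; `stratified = TRUE` splits
#' cases and controls separately instead.
#'
#' @param statuses Character vector of `"case"`/`"control"`.
#' @param n_folds Number of folds (default 10).
#' @param stratified Split within class (default `FALSE`).
#' @return Integer fold assignment (1..n_folds) per subject.
#' @export
make_folds <- function(statuses, n_folds = 10, stratified = FALSE) {
  n <- length(statuses)
  if (n < n_folds) abort("fewer subjects than folds")
  sizes <- rep(n %/% n_folds, n_folds) + c(rep(1, n %% n_folds),
                                           rep(0, n_folds - n %% n_folds))
  assign_ids <- function(idx) {
    k <- length(idx)
    sz <- rep(k %/% n_folds, n_folds) + c(rep(1, k %% n_folds),
                                          rep(0, n_folds - k %% n_folds))
    sample(rep.int(seq_len(n_folds), sz))
  }
  if (stratified) {
    fold <- integer(n)
    for (cl in c("case", "control")) {
      idx <- which(statuses == cl)
      fold[idx] <- assign_ids(idx)
    }
    return(fold)
  }
  for (attempt in seq_len(100)) {
    fold <- sample(rep.int(seq_len(n_folds), sizes))
    ok <- all(vapply(seq_len(n_folds), function(f) {
      s <- statuses[fold == f]
      any(s == "case") && any(s == "control")
    }, logical(1)))
    if (ok) return(fold)
  }
  abort("could not draw a partition with both classes in every fold (100 attempts)")
}

#' Repeated 10-fold internal cross-validation of one model
#'
#' Partitions the cohort into `n_folds` random near-equal folds; each
#' fold in turn is the validation set and the rest the training set.
#' With `refit = "full"` (default) the minor-allele assignment, the
#' per-SNP weights and the p-value SNP selection are re-estimated within
#' each training fold, so no validation label touches any trained
#' component; the LD-pruned sets are reused from the whole cohort since
#' pruning never sees phenotypes.  `refit = "none"` reuses the
#' whole-cohort weights and SNP list (an intentionally leaky variant for
#' comparison).
#'
#' @param cohort A QC'd [geno_cohort()].
#' @param spec One grid row (from [build_model_grid()]) or a list with
#'   `score_type`, `filter_kind`, `maf_cutoff`, `r2_threshold`,
#'   `p_threshold` (and `snp_ids` for `refit = "none"`).
#' @param trained Optional whole-cohort [train_risk_model()] result
#'   (reused for the pruned sets and the leaky variant; computed if
#'   missing).
#' @param n_folds,n_repeats Folds per pass and number of repeated
#'   passes (defaults 10 and 1).
#' @param refit `"full"` or `"none"`.
#' @param stratified Passed to [make_folds()].
#' @return A list of class `ma_internal_cv`: `mean_auc`, `mean_tpr`,
#'   `per_fold` (tibble with `repeat_`, `fold`, `n_valid`, `auc`, `tpr`).
#' @export
internal_cv <- function(cohort, spec, trained = NULL, n_folds = 10,
                        n_repeats = 1, refit = c("full", "none"),
                        stratified = FALSE) {
  refit <- match.arg(refit)
  if (is_tibble(spec)) {
    stopifnot(nrow(spec) == 1)
    spec <- as.list(spec)
    spec$snp_ids <- spec$snp_ids[[1]]
  }
  need_prune <- identical(spec$filter_kind, "ld_independent")
  if (is.null(trained)) {
    trained <- train_risk_model(cohort, r2_thresholds = if (need_prune)
      spec$r2_threshold else numeric(), prune = need_prune)
  }
  pruned_ids <- if (need_prune) {
    trained$pruned[[format_r2(spec$r2_threshold)]] %||%
      abort("`trained` lacks the pruned set for this r2 threshold")
  } else NULL
  rows <- purrr::map(seq_len(n_repeats), function(rep_) {
    fold <- make_folds(cohort$subjects$status, n_folds, stratified)
    purrr::map(seq_len(n_folds), function(f) {
      tr <- subset_cohort(cohort, subjects = fold != f)
      va <- subset_cohort(cohort, subjects = fold == f)
      if (refit == "full") {
        ma <- assign_minor_alleles(tr)
        w <- fit_snp_weights(tr, ma)
        ok <- w$usable & !is.na(w$p_value) & w$p_value < spec$p_threshold
        ids <- if (need_prune) {
          intersect(pruned_ids, w$snp_id[ok])
        } else {
          w$snp_id[ok & !is.na(w$maf) & w$maf < spec$maf_cutoff]
        }
      } else {
        ma <- trained$ma
        w <- trained$weights
        ids <- spec$snp_ids
      }
      if (!length(ids)) {
        return(tibble(repeat_ = rep_, fold = f, n_valid = nrow(va$dosage),
                      auc = NA_real_, tpr = NA_real_))
      }
      sv <- if (spec$score_type == "wgrs") {
        compute_wgrs(va, ma, w, ids)
      } else {
        compute_prs(va, ma, w, ids)
      }
      tibble(repeat_ = rep_, fold = f, n_valid = nrow(va$dosage),
             auc = score_auc(sv$score, sv$status)$auc,
             tpr = tpr_full_specificity(sv$score, sv$status)$tpr)
    })
  })
  per_fold <- dplyr::bind_rows(purrr::flatten(rows))
  structure(list(mean_auc = mean(per_fold$auc, na.rm = TRUE),
                 mean_tpr = mean(per_fold$tpr, na.rm = TRUE),
                 per_fold = per_fold, refit = refit),
            class = "ma_internal_cv")
}

#' @export
print.ma_internal_cv <- function(x, ...) {
  cat(sprintf("<ma_internal_cv> %d fold-evaluations; mean AUC %.4f, mean TPR %.4f (refit: %s)\n",
              nrow(x$per_fold), x$mean_auc, x$mean_tpr, x$refit))
  invisible(x)
}
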