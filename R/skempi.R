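# SKEMPI-style mutation tables, ddG ground truth, splits and metrics.

GAS_CONSTANT_KCAL <- 1.9872e-3  # kcal / (mol K)

RELIABLE_METHODS <- c("ITC", "SPR", "SP", "FL", "SFFL")
RELIABLE_METHOD_NAMES <- c(
  ITC = "Isothermal Titration Calorimetry",
  SPR = "Surface Plasmon Resonance",
  SP = "Spectroscopy",
  FL = "Fluorescence",
  SFFL = "Stopped-Flow Fluorimetry"
)

#' Binding free-energy change from dissociation constants
#'
#' `dG = R T ln(Kd)` per state and `ddG = dG(mut) - dG(wt)` with
#' `R = 1.9872e-3` kcal/(mol K); positive values destabilize binding.
#'
#' @param kd_wt,kd_mut Dissociation constants in M (> 0, vectorized).
#' @param temperature Temperature in K (default 298).
#' @return ddG in kcal/mol.
#' @export
#' @examples
#' ddg_from_affinities(1e-9, 1e-8)  # ~ +1.364 (R*T*ln 10)
ddg_from_affinities <- function(kd_wt, kd_mut, temperature = 298) {
  if (any(!is.finite(kd_wt)) || any(!is.finite(kd_mut)) ||
      any(kd_wt <= 0) || any(kd_mut <= 0))
    stop("dissociation constants must be positive and finite")
  if (any(temperature <= 0)) stop("temperature must be positive (K)")
  GAS_CONSTANT_KCAL * temperature * (log(kd_mut) - log(kd_wt))
}

# SKEMPI mutation string, e.g. "KI38A": wt aa, chain, position(+icode), mut.
parse_mutation_string <- function(s) {
  m <- regmatches(s, regexec("^([A-Y])([A-Za-z0-9])(\\d+)([A-Za-z]?)([A-Y])$",
                             s))[[1]]
  if (length(m) == 0) return(NULL)
  icode <- m[5]
  # a trailing letter before the target aa is an insertion code
  list(wt = m[2], chain = m[3], resno = as.integer(m[4]),
       icode = icode, mut = m[6])
}

sanitize_temperature <- function(x) {
  # SKEMPI temperature strings may carry annotations, e.g. "298(assumed)"
  t <- suppressWarnings(as.numeric(gsub("[^0-9.]", "", as.character(x))))
  t[!is.finite(t) | t <= 0] <- 298
  t
}

#' Parse a SKEMPI v2.0-style mutation table
#'
#' Reads the semicolon-separated dialect (columns `#Pdb`,
#' `Mutation(s)_cleaned`, `Affinity_wt_parsed`, `Affinity_mut_parsed`,
#' `Temperature`, `Method`, optionally `Hold_out_type`), keeps single-point
#' mutations measured by an allowed method with positive affinities,
#' derives ddG via [ddg_from_affinities()], and aggregates replicate
#' measurements of the same (complex, mutation) by the median ddG.
#' Every dropped row is logged with a reason in the `log` attribute.
#'
#' @param path File path.
#' @param allowed_methods Method codes to keep (default: the five reliable
#'   techniques ITC, SPR, SP, FL, SFFL).
#' @return data.frame of mutation records: `complex_id`, `pdb`, `chain`,
#'   `resno`, `icode`, `wt`, `mut`, `kd_wt`, `kd_mut`, `temperature`,
#'   `method`, `ddg`, `function_class`, `n_replicates`; attribute `log`
#'   holds the per-row filtering decisions.
#' @export
parse_skempi <- function(path, allowed_methods = RELIABLE_METHODS) {
  if (!file.exists(path)) stop("SKEMPI table not found: ", path)
  raw <- utils::read.csv2(path, sep = ";", stringsAsFactors = FALSE,
                          check.names = FALSE, comment.char = "")
  need <- c("#Pdb", "Mutation(s)_cleaned", "Affinity_wt_parsed",
            "Affinity_mut_parsed", "Temperature", "Method")
  missing <- setdiff(need, names(raw))
  if (length(missing) > 0)
    stop("SKEMPI table lacks column(s): ", paste(missing, collapse = ", "))

  log <- character(nrow(raw))
  keep <- rep(TRUE, nrow(raw))
  recs <- vector("list", nrow(raw))
  for (i in seq_len(nrow(raw))) {
    mut_field <- raw[["Mutation(s)_cleaned"]][i]
    if (grepl(",", mut_field)) {
      keep[i] <- FALSE; log[i] <- "multi-point mutation"; next
    }
    if (!(raw$Method[i] %in% allowed_methods)) {
      keep[i] <- FALSE
      log[i] <- paste0("method not allowed: ", raw$Method[i]); next
    }
    kd_wt <- suppressWarnings(as.numeric(raw[["Affinity_wt_parsed"]][i]))
    kd_mut <- suppressWarnings(as.numeric(raw[["Affinity_mut_parsed"]][i]))
    if (!is.finite(kd_wt) || !is.finite(kd_mut) ||
        kd_wt <= 0 || kd_mut <= 0) {
      keep[i] <- FALSE; log[i] <- "missing/non-positive affinity"; next
    }
    pm <- parse_mutation_string(trimws(mut_field))
    if (is.null(pm)) {
      keep[i] <- FALSE
      log[i] <- paste0("malformed mutation string: ", mut_field)
      warning("row ", i, ": malformed mutation string '", mut_field, "'")
      next
    }
    if (pm$wt == pm$mut) {
      keep[i] <- FALSE; log[i] <- "identity substitution"; next
    }
    temp <- sanitize_temperature(raw$Temperature[i])
    recs[[i]] <- data.frame(
      complex_id = raw[["#Pdb"]][i],
      pdb = substr(raw[["#Pdb"]][i], 1, 4),
      chain = pm$chain, resno = pm$resno, icode = pm$icode,
      wt = pm$wt, mut = pm$mut,
      kd_wt = kd_wt, kd_mut = kd_mut, temperature = temp,
      method = raw$Method[i],
      ddg = ddg_from_affinities(kd_wt, kd_mut, temp),
      function_class = if ("Hold_out_type" %in% names(raw))
        classify_function(raw[["Hold_out_type"]][i]) else "other",
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, recs[keep])
  if (is.null(out)) out <- data.frame()
  log_df <- data.frame(row = seq_len(nrow(raw)), kept = keep,
                       reason = ifelse(keep, "", log),
                       stringsAsFactors = FALSE)

  # replicate aggregation: median ddG per (complex, mutation)
  if (nrow(out) > 0) {
    mkey <- paste(out$complex_id, out$chain, out$resno, out$icode,
                  out$wt, out$mut)
    agg_ddg <- tapply(out$ddg, mkey, stats::median)
    n_rep <- tapply(out$ddg, mkey, length)
    first <- !duplicated(mkey)
    out <- out[first, , drop = FALSE]
    out$ddg <- as.numeric(agg_ddg[mkey[first]])
    out$n_replicates <- as.integer(n_rep[mkey[first]])
    rownames(out) <- NULL
  }
  attr(out, "log") <- log_df
  out
}

classify_function <- function(x) {
  x <- toupper(as.character(x))
  ifelse(grepl("AB/AG|ANTIBODY", x), "AB/AG",
         ifelse(grepl("PR/PI|PROTEASE", x), "Pr/PI",
                ifelse(grepl("TCR", x), "TCR/pMHC", "other")))
}

#' Build a train/test split plan
#'
#' Mutation-based: seeded k-fold partition of the records, each record in
#' exactly one test fold. Complex-based: whole complexes are sampled into
#' the held-out set, so no complex id ever appears on both sides.
#'
#' @param records Mutation table from [parse_skempi()] (needs
#'   `complex_id`).
#' @param level `"mutation"` or `"complex"`.
#' @param k Number of folds (mutation level; default 10).
#' @param holdout_fraction Fraction of complexes held out (complex level;
#'   default 0.2).
#' @param seed Seed; identical seeds give identical plans.
#' @return A `split_plan`: for mutation level, `fold` (integer per
#'   record); for complex level, `test_complexes` plus logical `in_test`.
#' @export
make_split <- function(records, level = c("mutation", "complex"),
                       k = 10, holdout_fraction = 0.2, seed = 1L) {
  level <- match.arg(level)
  n <- nrow(records)
  if (n == 0) stop("no records to split")
  set.seed(seed)
  if (level == "mutation") {
    fold <- sample(rep(seq_len(k), length.out = n))
    plan <- list(level = level, k = k, fold = fold, seed = seed)
  } else {
    cx <- unique(records$complex_id)
    if (length(cx) < 2)
      stop("complex-based split needs at least 2 complexes")
    n_test <- max(1, round(holdout_fraction * length(cx)))
    test_cx <- sort(sample(cx, n_test))
    plan <- list(level = level, test_complexes = test_cx,
                 in_test = records$complex_id %in% test_cx, seed = seed)
  }
  class(plan) <- "split_plan"
  plan
}

#' @export
print.split_plan <- function(x, ...) {
  if (x$level == "mutation")
    cat(sprintf("<split_plan> mutation-based %d-fold (seed %d)\n",
                x$k, x$seed))
  else
    cat(sprintf("<split_plan> complex-based, %d held-out complexes (seed %d)\n",
                length(x$test_complexes), x$seed))
  invisible(x)
}

#' Write / read a split plan as JSON-free plain text
#'
#' @param plan A `split_plan`.
#' @param path Output path (.rds used for fidelity, plus a .txt summary).
#' @return `path`, invisibly.
#' @export
save_split <- function(plan, path) {
  saveRDS(plan, path)
  invisible(path)
}

#' Restrict training records by sequence identity to the test complexes
#'
#' Given a precomputed pairwise identity matrix between complexes (the
#' package does not align sequences itself), keeps the training records
#' whose complex shares less than `cutoff` identity with every test
#' complex.
#'
#' @param records Mutation table (needs `complex_id`).
#' @param identity Numeric matrix with complex ids as dimnames; entries in
#'   `[0, 1]`.
#' @param test_complexes Complex ids of the held-out set.
#' @param cutoff Maximum allowed identity (default 0.3).
#' @return The filtered records (rows whose complex passes the cutoff).
#' @export
filter_by_identity <- function(records, identity, test_complexes,
                               cutoff = 0.3) {
  stopifnot(is.matrix(identity), !is.null(rownames(identity)))
  train_cx <- setdiff(unique(records$complex_id), test_complexes)
  missing <- setdiff(c(train_cx, test_complexes), rownames(identity))
  if (length(missing) > 0)
    stop("identity matrix lacks complex(es): ",
         paste(missing, collapse = ", "))
  keep_cx <- train_cx[apply(
    identity[train_cx, test_complexes, drop = FALSE], 1,
    function(r) all(r < cutoff))]
  records[records$complex_id %in% keep_cx, , drop = FALSE]
}

#' Evaluate ddG predictions
#'
#' Pearson correlation coefficient and root-mean-squared error, overall
#' and (optionally) per stratum. Strata with fewer than 2 points are
#' reported with `NA` metrics rather than silently dropped.
#'
#' @param predictions,truths Equal-length numeric vectors.
#' @param strata Optional labels (e.g. region, functional class,
#'   size-change class) for stratified reporting.
#' @return List with `overall` (`pcc`, `rmse`, `n`) and, when `strata` is
#'   given, `by_stratum` (data.frame).
#' @export
#' @examples
#' evaluate_predictions(c(0, 1, 4), c(0, 1, 2))
evaluate_predictions <- function(predictions, truths, strata = NULL) {
  if (length(predictions) != length(truths))
    stop("predictions and truths differ in length")
  one <- function(p, t) {
    n <- length(p)
    if (n < 2) return(c(pcc = NA_real_, rmse = NA_real_, n = n))
    c(pcc = stats::cor(p, t), rmse = sqrt(mean((p - t)^2)), n = n)
  }
  out <- list(overall = as.list(one(predictions, truths)))
  if (!is.null(strata)) {
    strata <- as.character(strata)
    levs <- unique(strata)
    tab <- do.call(rbind, lapply(levs, function(s) {
      sel <- strata == s
      data.frame(stratum = s,
                 t(one(predictions[sel], truths[sel])),
                 stringsAsFactors = FALSE)
    }))
    out$by_stratum <- tab
  }
  out
}

#' Write predictions as a TSV
#'
#' @param records Mutation table rows matching the predictions.
#' @param predictions Predicted ddG values.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_predictions <- function(records, predictions, path) {
  stopifnot(nrow(records) == length(predictions))
  out <- data.frame(complex = records$complex_id,
                    mutation = paste0(records$wt, records$chain,
                                      records$resno, records$icode,
                                      records$mut),
                    predicted_ddg = predictions,
                    truth_ddg = records$ddg)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
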