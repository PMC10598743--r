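#' Random-forest classifier configuration
#'
#' @param mtry Features tried per split (default 5; capped at the number of
#'   features of the category being trained).
#' @param ntrees Number of trees (default 2000).
#' @param train_fraction Fraction of rows in the stratified training split
#'   (default 0.75).
#' @param nodesize Minimum terminal-node size (default 10). Fully grown
#'   trees (nodesize 1) give noisy class-probability estimates; a moderate
#'   node size is the standard choice when the forest's vote fractions are
#'   consumed as ranking scores for ROC analysis.
#' @param seed Integer seed controlling the split and the forest.
#' @return An `rfc_config` list.
#' @export
rfc_config <- function(mtry = 5L, ntrees = 2000L, train_fraction = 0.75,
                       nodesize = 10L, seed = 1L) {
  cfg <- list(mtry = as.integer(mtry), ntrees = as.integer(ntrees),
              train_fraction = train_fraction,
              nodesize = as.integer(nodesize), seed = as.integer(seed))
  stopifnot(cfg$mtry >= 1L, cfg$ntrees >= 1L, cfg$nodesize >= 1L,
            cfg$train_fraction > 0, cfg$train_fraction < 1)
  class(cfg) <- "rfc_config"
  cfg
}

FEATURE_OFFSETS <- -4:4

#' Extract per-position feature vectors for pause classification
#'
#' Builds one row per candidate position (real or shuffled pause) with
#' feature columns grouped into named categories:
#' \describe{
#'   \item{distance_to_polya}{distance to the nearest upstream poly(A) site
#'     (sentinel `utr3_len` when none exists in the window) and the site
#'     counts in the five 10-nt bins 0-50 nt upstream.}
#'   \item{sequence_context}{one-hot sense-strand nucleotides at offsets
#'     -4..+4 around the position (all-zero where the context leaves the
#'     chromosome).}
#'   \item{other named categories}{one column per supplied per-position
#'     genomic track (e.g. `dna_shape`, `chromatin`, `ctd`), looked up at the
#'     genomic coordinate.}
#' }
#'
#' @param candidates Pause set `data.frame` (real and shuffled rows, with
#'   `unit_id, chrom, strand, pos0, rel_pos, provenance`).
#' @param polya Poly(A) profile with `unit_id`, `rel_pos`.
#' @param genome `DNAStringSet`.
#' @param tracks Named list: category -> list(chrom -> numeric vector), as
#'   from [simulate_feature_tracks()]. May be empty.
#' @param utr3_len Sentinel distance for positions lacking an upstream site
#'   (default 400).
#' @return `data.frame` of features plus a `label` factor
#'   (`real`/`shuffled`); attribute `categories` maps category names to
#'   their column names.
#' @export
extract_features <- function(candidates, polya, genome, tracks = list(),
                             utr3_len = 400L) {
  n <- nrow(candidates)
  cats <- list()

  d <- nearest_upstream_distance(candidates, polya)
  d[is.na(d)] <- utr3_len
  bins <- upstream_bin_counts(candidates, polya)
  colnames(bins) <- paste0("pa_bin_", UPSTREAM_BINS[-6L], "_", UPSTREAM_BINS[-1L])
  out <- data.frame(dist_polya = d, bins, check.names = FALSE)
  cats$distance_to_polya <- colnames(out)

  ctx <- sense_context(candidates, genome, min(FEATURE_OFFSETS),
                       max(FEATURE_OFFSETS))
  seq_cols <- character(0)
  for (k in seq_along(FEATURE_OFFSETS)) {
    base_k <- substring(ctx, k, k)
    for (b in c("A", "C", "G", "T")) {
      cn <- sprintf("seq_%s_%s",
                    sub("-", "m", as.character(FEATURE_OFFSETS[k])), b)
      out[[cn]] <- as.integer(!is.na(base_k) & base_k == b)
      seq_cols <- c(seq_cols, cn)
    }
  }
  cats$sequence_context <- seq_cols

  for (cat in names(tracks)) {
    vals <- vapply(seq_len(n), function(i) {
      v <- tracks[[cat]][[candidates$chrom[i]]]
      if (is.null(v)) stop("track '", cat, "' missing chromosome ",
                           candidates$chrom[i])
      v[candidates$pos0[i] + 1L]
    }, numeric(1))
    out[[cat]] <- vals
    cats[[cat]] <- cat
  }

  out$label <- factor(candidates$provenance, levels = c("shuffled", "real"))
  if (anyNA(out$label)) stop("candidates must carry real/shuffled provenance")
  attr(out, "categories") <- cats
  out
}

select_category <- function(features, category) {
  cats <- attr(features, "categories")
  cols <- if (identical(category, "all")) unlist(cats, use.names = FALSE)
  else {
    if (!category %in% names(cats))
      stop("unknown feature category: ", category, " (have: ",
           paste(names(cats), collapse = ", "), ")")
    cats[[category]]
  }
  features[, cols, drop = FALSE]
}

forest_auc <- function(xtr, ytr, xte, yte, config) {
  rf <- randomForest::randomForest(
    x = xtr, y = ytr, ntree = config$ntrees,
    mtry = min(config$mtry, ncol(xtr)), nodesize = config$nodesize)
  prob <- stats::predict(rf, xte, type = "prob")[, "real"]
  as.numeric(pROC::auc(pROC::roc(response = yte, predictor = prob,
                                 levels = c("shuffled", "real"),
                                 direction = "<", quiet = TRUE)))
}

#' Train a random forest and evaluate held-out AUC
#'
#' Trains on a stratified `train_fraction` split (per-class sampling, no
#' resampling of the minority class; AUC is imbalance-robust) and reports the
#' area under the ROC curve on the held-out rows. An AUC of 0.5 corresponds
#' to random classification.
#'
#' @param features Feature matrix from [extract_features()].
#' @param category One category name or `"all"`.
#' @param config An [rfc_config()].
#' @return Held-out AUC (numeric scalar).
#' @export
train_eval_rfc <- function(features, category = "all", config = rfc_config()) {
  y <- features$label
  if (nlevels(droplevels(y)) < 2L) stop("single-class input")
  x <- select_category(features, category)
  set.seed(config$seed)
  tr <- unlist(lapply(levels(y), function(lv) {
    idx <- which(y == lv)
    sample(idx, floor(length(idx) * config$train_fraction))
  }), use.names = FALSE)
  forest_auc(x[tr, , drop = FALSE], droplevels(y[tr]),
             x[-tr, , drop = FALSE], droplevels(y[-tr]), config)
}

#' Cross-strain AUC matrix
#'
#' Off-diagonal cell (i, j): a forest trained on all rows of strain i,
#' evaluated on all rows of strain j. Diagonal cells use the within-strain
#' stratified 75/25 split ([train_eval_rfc()]). All matrices must share the
#' same feature columns.
#'
#' @param strain_features Named list of feature matrices
#'   ([extract_features()]).
#' @param category One category name or `"all"`.
#' @param config An [rfc_config()].
#' @return Numeric AUC matrix (train strain = rows, test strain = columns).
#' @export
cross_strain_auc <- function(strain_features, category = "all",
                             config = rfc_config()) {
  stopifnot(length(strain_features) >= 2L)
  cols <- lapply(strain_features, function(f) colnames(select_category(f, category)))
  if (length(unique(cols)) != 1L)
    stop("feature matrices have mismatched columns")
  nm <- names(strain_features)
  if (is.null(nm)) nm <- paste0("strain", seq_along(strain_features))
  n <- length(strain_features)
  m <- matrix(NA_real_, n, n, dimnames = list(train = nm, test = nm))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) {
      m[i, j] <- train_eval_rfc(strain_features[[i]], category, config)
    } else {
      set.seed(config$seed)
      m[i, j] <- forest_auc(select_category(strain_features[[i]], category),
                            strain_features[[i]]$label,
                            select_category(strain_features[[j]], category),
                            strain_features[[j]]$label, config)
    }
  }
  m
}

#' PCA of strains over shared 3' UTR pause positions
#'
#' Each strain is encoded as a binary vector over the union of all strains'
#' 3' UTR pause positions (1 = position paused in that strain); vectors are
#' centered and projected on the first two principal components. Strains
#' with more common pause sites land closer together.
#'
#' @param pause_sets Named list (>= 3) of pause sets.
#' @return List with `coords` (strains x PC1-2 matrix), `var_explained`
#'   (fractions for PC1-2) and `degenerate` (`TRUE` when all strains have
#'   identical pause sets, in which case coordinates are all zero).
#' @export
pca_strains <- function(pause_sets) {
  stopifnot(length(pause_sets) >= 3L)
  nm <- names(pause_sets)
  if (is.null(nm)) nm <- paste0("strain", seq_along(pause_sets))
  keys <- lapply(pause_sets, function(p) {
    p <- p[p$region == "utr3", , drop = FALSE]
    unique(paste(p$unit_id, p$rel_pos))
  })
  universe <- sort(unique(unlist(keys)))
  if (length(universe) == 0L) stop("no 3' UTR pauses in any strain")
  m <- do.call(rbind, lapply(keys, function(k) as.numeric(universe %in% k)))
  rownames(m) <- nm
  if (all(apply(m, 2L, function(col) length(unique(col)) == 1L)))
    return(list(coords = matrix(0, length(nm), 2L,
                                dimnames = list(nm, c("PC1", "PC2"))),
                var_explained = c(PC1 = 0, PC2 = 0), degenerate = TRUE))
  pc <- stats::prcomp(m, center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2 / sum(pc$sdev^2)
  k <- min(2L, ncol(pc$x))
  coords <- matrix(0, length(nm), 2L, dimnames = list(nm, c("PC1", "PC2")))
  coords[, seq_len(k)] <- pc$x[, seq_len(k)]
  list(coords = coords,
       var_explained = c(PC1 = ev[1], PC2 = if (length(ev) > 1) ev[2] else 0),
       degenerate = FALSE)
}

#' Shuffled-vs-shuffled classifier baseline
#'
#' Calibration control for the pause classifier: two independent sets of
#' uniformly drawn 3' UTR positions from the same synthetic strain (uncoupled
#' poly(A) profile, zero signal-to-noise feature tracks) are labeled as the
#' two classes and a forest is trained on all feature categories. Because the
#' classes are statistically identical, the held-out AUC estimates the
#' random-classification baseline of 0.5; systematic departures indicate
#' leakage in the feature extraction or evaluation.
#'
#' @param seed Integer seed controlling the simulated strain, both position
#'   draws, and (by default) the forest.
#' @param n_units Number of simulated units (default 50).
#' @param n_per_class Positions per class (default 1000).
#' @param config An [rfc_config()]; defaults to `rfc_config(seed = seed)`.
#' @return Held-out AUC.
#' @export
rfc_null_baseline <- function(seed, n_units = 50L, n_per_class = 1000L,
                              config = rfc_config(seed = seed)) {
  cfg <- sim_config(seed = seed, n_units = n_units,
                    polya_coupling = "uniform",
                    feature_snr = c(dna_shape = 0, chromatin = 0, ctd = 0))
  sim <- simulate_netseq(cfg)
  pa <- simulate_polya(sim$units, sim$truth, cfg)
  tracks <- simulate_feature_tracks(sim$truth, sim$units, cfg, sim$genome)
  a <- random_pause_set(sim$units, n_per_class, seed = seed + 1009L)
  b <- random_pause_set(sim$units, n_per_class, seed = seed + 2003L)
  a$provenance <- "real"
  fm <- extract_features(rbind(a, b), pa, sim$genome, tracks,
                         utr3_len = cfg$utr3_len)
  train_eval_rfc(fm, "all", config)
}
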