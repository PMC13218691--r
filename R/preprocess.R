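## Cohort I/O, cleaning, splitting, normalization and target construction.
## All normalization statistics are fitted on the training partition only;
## SDs are sample SDs (denominator n - 1) throughout.

IND_COLS <- c("speed", "endurance", "strength")
HIST_COLS <- paste0("hist_", IND_COLS)

#' Write a cohort to delimited text files
#'
#' Persists `genotypes.tsv` (id + one dosage column per marker),
#' `phenotypes.tsv` (id, speed, endurance, strength and, when present,
#' hist_speed, hist_endurance, hist_strength) and, when ground truth is
#' available, `truth.tsv`.  Missing cells are written as `NA`.
#'
#' @param cohort A `cohort`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  g <- data.frame(id = cohort$ids, cohort$genotypes, check.names = FALSE)
  colnames(g) <- c("id", paste0("m", seq_len(ncol(cohort$genotypes))))
  utils::write.table(g, file.path(dir, "genotypes.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  ph <- data.frame(id = cohort$ids, cohort$phenotypes, check.names = FALSE)
  if (!is.null(cohort$historical)) ph <- cbind(ph, cohort$historical)
  utils::write.table(ph, file.path(dir, "phenotypes.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  if (!is.null(cohort$true_genetic_value)) {
    tr <- data.frame(id = cohort$ids,
                     true_genetic_value = cohort$true_genetic_value,
                     true_noise_sd = cohort$true_noise_sd)
    utils::write.table(tr, file.path(dir, "truth.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
  }
  invisible(dir)
}

read_tsv_checked <- function(path) {
  header <- strsplit(readLines(path, n = 1), "\t", fixed = TRUE)[[1]]
  dupd <- unique(header[duplicated(header)])
  stop_if(length(dupd) > 0,
          "duplicated column name(s) in ", basename(path), ": ",
          paste(dupd, collapse = ", "))
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE, check.names = FALSE)
}

#' Read a cohort from genotype and phenotype tables
#'
#' Inner-joins the two tables on their `id` column (identity alignment);
#' rows present in only one file are dropped and reported.  When a
#' `truth.tsv` sits next to the phenotype file it is picked up too.
#'
#' @param genotype_path,phenotype_path Paths to TSV files, each with an
#'   `id` column.
#' @return A `cohort`; attribute `"dropped"` lists IDs found in only one
#'   file.
#' @export
read_cohort <- function(genotype_path, phenotype_path) {
  stop_if(!file.exists(genotype_path), "genotype file not found: ", genotype_path)
  stop_if(!file.exists(phenotype_path), "phenotype file not found: ", phenotype_path)
  g <- read_tsv_checked(genotype_path)
  ph <- read_tsv_checked(phenotype_path)
  stop_if(!"id" %in% colnames(g), "genotype file lacks an 'id' column")
  stop_if(!"id" %in% colnames(ph), "phenotype file lacks an 'id' column")
  g$id <- as.character(g$id); ph$id <- as.character(ph$id)
  common <- intersect(g$id, ph$id)
  stop_if(length(common) == 0, "no overlapping IDs between the two files")
  dropped <- union(setdiff(g$id, ph$id), setdiff(ph$id, g$id))
  ## keep genotype-file order for shared ids, preserving duplicates
  g2 <- g[g$id %in% common, , drop = FALSE]
  ph2 <- ph[match(g2$id, ph$id), , drop = FALSE]
  hist <- if (all(HIST_COLS %in% colnames(ph2)))
    ph2[, HIST_COLS, drop = FALSE]
  truth_path <- file.path(dirname(phenotype_path), "truth.tsv")
  tgv <- tns <- NULL
  if (file.exists(truth_path)) {
    tr <- read_tsv_checked(truth_path)
    tr <- tr[match(g2$id, as.character(tr$id)), , drop = FALSE]
    tgv <- tr$true_genetic_value; tns <- tr$true_noise_sd
  }
  cohort <- new_cohort(
    ids = g2$id,
    genotypes = as.matrix(g2[, setdiff(colnames(g2), "id"), drop = FALSE]),
    phenotypes = ph2[, IND_COLS, drop = FALSE],
    historical = hist, true_genetic_value = tgv, true_noise_sd = tns
  )
  attr(cohort, "dropped") <- dropped
  cohort
}

#' Clean a cohort
#'
#' Applies, in fixed order: (1) duplicate removal by ID, first occurrence
#' kept; (2) removal of rows with any missing genotype or phenotype cell;
#' (3) the three-standard-deviation rule per indicator — rows with
#' `|x - mean| > 3 * SD` removed, where mean and sample SD are computed once
#' over all rows surviving step 2 (a single pass; statistics are not
#' recomputed after removals).
#'
#' @param cohort A `cohort`.
#' @return The cleaned `cohort`; attribute `"report"` counts removals per
#'   rule and lists removed IDs.
#' @export
clean_cohort <- function(cohort) {
  stopifnot(inherits(cohort, "cohort"))
  report <- list(duplicates = 0L, missing = 0L, outliers = 0L,
                 removed_ids = character(0))
  keep_rows <- function(cohort, keep) {
    cohort$ids <- cohort$ids[keep]
    cohort$genotypes <- cohort$genotypes[keep, , drop = FALSE]
    cohort$phenotypes <- cohort$phenotypes[keep, , drop = FALSE]
    if (!is.null(cohort$historical))
      cohort$historical <- cohort$historical[keep, , drop = FALSE]
    if (!is.null(cohort$true_genetic_value))
      cohort$true_genetic_value <- cohort$true_genetic_value[keep]
    if (!is.null(cohort$true_noise_sd))
      cohort$true_noise_sd <- cohort$true_noise_sd[keep]
    cohort
  }
  dup <- duplicated(cohort$ids)
  report$duplicates <- sum(dup)
  report$removed_ids <- c(report$removed_ids, cohort$ids[dup])
  cohort <- keep_rows(cohort, !dup)

  miss <- rowSums(is.na(cohort$genotypes)) > 0 |
    rowSums(is.na(cohort$phenotypes)) > 0
  if (!is.null(cohort$historical))
    miss <- miss | rowSums(is.na(cohort$historical)) > 0
  report$missing <- sum(miss)
  report$removed_ids <- c(report$removed_ids, cohort$ids[miss])
  cohort <- keep_rows(cohort, !miss)

  out <- rep(FALSE, length(cohort$ids))
  for (col in IND_COLS) {
    x <- cohort$phenotypes[[col]]
    m <- mean(x); s <- stats::sd(x)
    if (is.finite(s) && s > 0) out <- out | (abs(x - m) > 3 * s)
  }
  report$outliers <- sum(out)
  report$removed_ids <- c(report$removed_ids, cohort$ids[out])
  cohort <- keep_rows(cohort, !out)
  stop_if(length(cohort$ids) == 0, "no rows remain after cleaning")
  attr(cohort, "report") <- report
  cohort
}

#' Split IDs into train / validation / test partitions
#'
#' Uniform random permutation under `seed`, then the first `floor(0.8 n)`
#' IDs go to train, the next `floor(0.1 n)` to validation and the remainder
#' to test (an 8:1:1 protocol at the individual level).
#'
#' @param ids Character vector of at least 10 unique IDs.
#' @param seed Integer seed.
#' @return A `split_index`: list of `train`, `validation`, `test` ID
#'   vectors plus the seed.
#' @export
split_cohort <- function(ids, seed = 42) {
  stop_if(length(ids) < 10, "need at least 10 IDs to split 8:1:1")
  perm <- with_seed(derive_seed(seed, 4L), sample(ids))
  n <- length(ids)
  n_tr <- floor(0.8 * n); n_va <- floor(0.1 * n)
  structure(list(
    train = perm[seq_len(n_tr)],
    validation = perm[n_tr + seq_len(n_va)],
    test = perm[(n_tr + n_va + 1):n],
    seed = as.integer(seed)
  ), class = "split_index")
}

#' Fit normalization parameters on the training partition
#'
#' Genotype columns get train-set min and max (for min--max scaling to
#' `[0, 1]`); indicators and historical indicators get train-set mean and
#' sample SD (for z-scoring); the potential-score mean and SD are fitted on
#' the train rows of the z-scored indicator average so that
#' [build_target()] has train mean 0 and SD 1.
#'
#' @param cohort A cleaned `cohort`.
#' @param split A `split_index` over `cohort$ids`.
#' @return A `norm_params` object.
#' @export
fit_normalizers <- function(cohort, split) {
  stopifnot(inherits(cohort, "cohort"), inherits(split, "split_index"))
  tr <- cohort$ids %in% split$train
  stop_if(sum(tr) < 2, "training partition too small to fit normalizers")
  G <- cohort$genotypes[tr, , drop = FALSE]
  gmin <- apply(G, 2, min); gmax <- apply(G, 2, max)
  ind_mean <- vapply(IND_COLS, function(c) mean(cohort$phenotypes[[c]][tr]), 0)
  ind_sd <- vapply(IND_COLS, function(c) stats::sd(cohort$phenotypes[[c]][tr]), 0)
  stop_if(any(ind_sd == 0) || any(!is.finite(ind_sd)),
          "degenerate cohort: an indicator has zero SD on the training split")
  hist_mean <- hist_sd <- NULL
  if (!is.null(cohort$historical)) {
    hist_mean <- vapply(HIST_COLS, function(c) mean(cohort$historical[[c]][tr]), 0)
    hist_sd <- vapply(HIST_COLS, function(c) stats::sd(cohort$historical[[c]][tr]), 0)
    stop_if(any(hist_sd == 0), "degenerate cohort: a historical indicator has zero SD")
  }
  ## potential score = mean of the three z-scored indicators, then
  ## re-standardized to train mean 0 / SD 1
  zt <- sapply(seq_along(IND_COLS), function(j)
    (cohort$phenotypes[[IND_COLS[j]]][tr] - ind_mean[j]) / ind_sd[j])
  raw <- rowMeans(zt)
  y_mean <- mean(raw); y_sd <- stats::sd(raw)
  stop_if(!is.finite(y_sd) || y_sd == 0, "degenerate cohort: potential score has zero SD")
  structure(list(
    g_min = gmin, g_max = gmax,
    ind_mean = ind_mean, ind_sd = ind_sd,
    hist_mean = hist_mean, hist_sd = hist_sd,
    y_mean = y_mean, y_sd = y_sd,
    constant_cols = which(gmax == gmin)
  ), class = "norm_params")
}

#' Build the potential-score target
#'
#' `y_i` is the mean of the three z-scored assessment-time indicators,
#' re-standardized with the train-set mean/SD stored in `params`, so the
#' train rows have mean 0 and sample SD 1.
#'
#' @param cohort A `cohort`.
#' @param params A `norm_params` fitted with [fit_normalizers()].
#' @return Numeric vector aligned to `cohort$ids`.
#' @export
build_target <- function(cohort, params) {
  stopifnot(inherits(params, "norm_params"))
  z <- sapply(seq_along(IND_COLS), function(j)
    (cohort$phenotypes[[IND_COLS[j]]] - params$ind_mean[j]) / params$ind_sd[j])
  z <- matrix(z, ncol = 3)
  (rowMeans(z) - params$y_mean) / params$y_sd
}

#' Apply normalizers and assemble the modelling dataset
#'
#' Min--max scales genotype columns with the train-set range (constant
#' columns map to 0; out-of-range values map outside `[0, 1]` without
#' clipping), z-scores historical indicators when
#' `features = "genotype+historical"`, builds the potential-score target
#' via [build_target()] and carries the z-scored assessment-time indicator
#' matrix for the planner's reward supervision.
#'
#' @param cohort A cleaned `cohort`.
#' @param params A `norm_params`.
#' @param split A `split_index`.
#' @param features `"genotype+historical"` (default when historical records
#'   exist) or `"genotype-only"`.
#' @return A `gap_dataset`: list with feature matrix `X`, target `y`,
#'   z-scored indicator matrix `y3`, `ids`, `params`, `split`, the
#'   genotype-feature column index `genotype_cols`, and ground-truth
#'   vectors when the cohort carries them.
#' @export
apply_normalizers <- function(cohort, params, split,
                              features = c("genotype+historical",
                                           "genotype-only")) {
  stopifnot(inherits(cohort, "cohort"), inherits(params, "norm_params"))
  features <- match.arg(features)
  G <- cohort$genotypes
  rngv <- params$g_max - params$g_min
  Xg <- sweep(G, 2, params$g_min)
  Xg <- sweep(Xg, 2, ifelse(rngv == 0, 1, rngv), "/")
  if (length(params$constant_cols)) Xg[, params$constant_cols] <- 0
  colnames(Xg) <- colnames(G) %||% paste0("m", seq_len(ncol(G)))
  X <- Xg
  if (features == "genotype+historical") {
    if (is.null(cohort$historical))
      stop("cohort has no historical records; use features = \"genotype-only\"",
           call. = FALSE)
    H <- sapply(seq_along(HIST_COLS), function(j)
      (cohort$historical[[HIST_COLS[j]]] - params$hist_mean[j]) / params$hist_sd[j])
    colnames(H) <- HIST_COLS
    X <- cbind(X, H)
  }
  y3 <- sapply(seq_along(IND_COLS), function(j)
    (cohort$phenotypes[[IND_COLS[j]]] - params$ind_mean[j]) / params$ind_sd[j])
  colnames(y3) <- IND_COLS
  structure(list(
    X = X, y = build_target(cohort, params), y3 = y3,
    ids = cohort$ids, params = params, split = split,
    genotype_cols = seq_len(ncol(Xg)), features = features,
    true_genetic_value = cohort$true_genetic_value,
    true_noise_sd = cohort$true_noise_sd
  ), class = "gap_dataset")
}

#' @export
print.gap_dataset <- function(x, ...) {
  cat("gap_dataset:", nrow(x$X), "individuals x", ncol(x$X), "features (",
      x$features, ")\n")
  cat("  split:", length(x$split$train), "train /",
      length(x$split$validation), "validation /",
      length(x$split$test), "test\n")
  invisible(x)
}

#' Invert the feature normalization
#'
#' Maps normalized feature values back to the original scale; exact (to
#' numerical precision) for non-constant columns.
#'
#' @param X Normalized feature matrix with the column layout produced by
#'   [apply_normalizers()].
#' @param params The `norm_params` used to normalize.
#' @param genotype_cols Indices of genotype columns within `X`.
#' @return Matrix on the original scale.
#' @export
inverse_normalize <- function(X, params, genotype_cols = seq_len(length(params$g_min))) {
  out <- X
  rngv <- params$g_max - params$g_min
  out[, genotype_cols] <- sweep(
    sweep(X[, genotype_cols, drop = FALSE], 2, ifelse(rngv == 0, 1, rngv), "*"),
    2, params$g_min, "+")
  hist_cols <- setdiff(seq_len(ncol(X)), genotype_cols)
  if (length(hist_cols) && !is.null(params$hist_mean)) {
    out[, hist_cols] <- sweep(
      sweep(X[, hist_cols, drop = FALSE], 2, params$hist_sd, "*"),
      2, params$hist_mean, "+")
  }
  out
}

#' Add Gaussian measurement noise to genotype features
#'
#' Robustness augmentation: adds i.i.d. `N(0, sd^2)` noise to the genotype
#' feature columns only (historical indicator columns are untouched).
#'
#' @param dataset A `gap_dataset`, or a plain numeric matrix.
#' @param sd Noise standard deviation (`>= 0`).
#' @param seed Integer seed.
#' @return Same type as the input, with perturbed genotype features.
#' @export
inject_feature_noise <- function(dataset, sd, seed = 42) {
  stop_if(sd < 0, "sd must be nonnegative")
  if (sd == 0) return(dataset)
  if (is.matrix(dataset)) {
    return(dataset + with_seed(derive_seed(seed, 5L),
      matrix(stats::rnorm(length(dataset), sd = sd),
             nrow(dataset), ncol(dataset))))
  }
  stopifnot(inherits(dataset, "gap_dataset"))
  gc_ <- dataset$genotype_cols
  noise <- with_seed(derive_seed(seed, 5L),
    matrix(stats::rnorm(nrow(dataset$X) * length(gc_), sd = sd),
           nrow(dataset$X), length(gc_)))
  dataset$X[, gc_] <- dataset$X[, gc_] + noise
  dataset
}

#' Run the full preprocessing pipeline
#'
#' Clean, split, fit normalizers on train, normalize, build the target.
#'
#' @param cohort A raw `cohort`.
#' @param seed Split seed.
#' @param features Feature-set switch, see [apply_normalizers()].
#' @return A `gap_dataset`; attribute `"report"` carries the cleaning
#'   report.
#' @export
build_dataset <- function(cohort, seed = 42,
                          features = c("genotype+historical", "genotype-only")) {
  features <- match.arg(features)
  cleaned <- clean_cohort(cohort)
  split <- split_cohort(cleaned$ids, seed)
  params <- fit_normalizers(cleaned, split)
  ds <- apply_normalizers(cleaned, params, split, features)
  attr(ds, "report") <- attr(cleaned, "report")
  ds
}

## row indices of a partition
split_rows <- function(dataset, part = c("train", "validation", "test")) {
  part <- match.arg(part)
  which(dataset$ids %in% dataset$split[[part]])
}

#' Persist a processed dataset as plain text
#'
#' Writes `X.tsv`, `y.tsv`, `norm_params.json`, `split.json` and
#' `removals.log` into a directory; [load_dataset()] restores it.
#'
#' @param dataset A `gap_dataset`.
#' @param dir Target directory.
#' @return `dir`, invisibly.
#' @export
save_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(
    data.frame(id = dataset$ids, dataset$X, check.names = FALSE),
    file.path(dir, "X.tsv"), sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(
    data.frame(id = dataset$ids, y = dataset$y, dataset$y3, check.names = FALSE),
    file.path(dir, "y.tsv"), sep = "\t", row.names = FALSE, quote = FALSE)
  p <- dataset$params
  jsonlite::write_json(
    lapply(unclass(p), function(v) if (is.null(v)) NULL else unname(v)),
    file.path(dir, "norm_params.json"), auto_unbox = TRUE, digits = NA,
    null = "null")
  jsonlite::write_json(
    list(train = dataset$split$train, validation = dataset$split$validation,
         test = dataset$split$test, seed = dataset$split$seed,
         features = dataset$features,
         genotype_cols = dataset$genotype_cols),
    file.path(dir, "split.json"), digits = NA)
  rep <- attr(dataset, "report")
  writeLines(
    if (is.null(rep)) character(0) else
      c(sprintf("duplicates\t%d", rep$duplicates),
        sprintf("missing\t%d", rep$missing),
        sprintf("outliers\t%d", rep$outliers),
        sprintf("removed\t%s", paste(rep$removed_ids, collapse = ","))),
    file.path(dir, "removals.log"))
  invisible(dir)
}

#' @rdname save_dataset
#' @param dir Directory written by [save_dataset()].
#' @export
load_dataset <- function(dir) {
  Xdf <- read_tsv_checked(file.path(dir, "X.tsv"))
  ydf <- read_tsv_checked(file.path(dir, "y.tsv"))
  pj <- jsonlite::read_json(file.path(dir, "norm_params.json"), simplifyVector = TRUE)
  sj <- jsonlite::read_json(file.path(dir, "split.json"), simplifyVector = TRUE)
  params <- structure(pj, class = "norm_params")
  split <- structure(list(train = sj$train, validation = sj$validation,
                          test = sj$test, seed = sj$seed), class = "split_index")
  structure(list(
    X = as.matrix(Xdf[, -1, drop = FALSE]),
    y = ydf$y,
    y3 = as.matrix(ydf[, IND_COLS, drop = FALSE]),
    ids = as.character(Xdf$id), params = params, split = split,
    genotype_cols = sj$genotype_cols, features = sj$features
  ), class = "gap_dataset")
}
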