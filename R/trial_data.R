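#' Construct a multi-environment trial data set
#'
#' A `trial_data` object holds long-format phenotype records from a
#' (possibly unbalanced) multi-environment trial: one row per plot, with a
#' genotype label, an environment label, a block (replicate) label and a
#' numeric response. Blocks are always treated as nested within
#' environments, so the same block label in two environments denotes two
#' distinct block cells.
#'
#' @param genotype,environment,block vectors of labels (coerced to character).
#' @param response numeric response values (e.g. grain yield in t/ha).
#' @return An object of class `trial_data`: a list with the record table
#'   (`records`), the sorted label indices (`genotypes`, `environments`,
#'   `block_cells`), the integer index vectors used by the samplers
#'   (`gi`, `ei`, `bi`), and the counts `g`, `e`, `n`.
#' @export
trial_data <- function(genotype, environment, block, response) {
  genotype <- as.character(genotype)
  environment <- as.character(environment)
  block <- as.character(block)
  response <- as.numeric(response)
  n <- length(response)
  if (n == 0L) stop("empty trial: no records", call. = FALSE)
  if (length(genotype) != n || length(environment) != n || length(block) != n)
    stop("genotype, environment, block and response must have equal length",
         call. = FALSE)
  keep <- is.finite(response)
  dropped <- sum(!keep)
  if (dropped) {
    genotype <- genotype[keep]; environment <- environment[keep]
    block <- block[keep]; response <- response[keep]
    n <- length(response)
    if (n == 0L) stop("empty trial: all responses missing", call. = FALSE)
  }
  genotypes <- sort(unique(genotype))
  environments <- sort(unique(environment))
  # block cells are environment x block combinations (nesting)
  cell_lab <- paste(environment, block, sep = ":")
  block_cells <- sort(unique(cell_lab))
  out <- list(
    records = data.frame(genotype = genotype, environment = environment,
                         block = block, response = response,
                         stringsAsFactors = FALSE),
    genotypes = genotypes, environments = environments,
    block_cells = block_cells,
    gi = match(genotype, genotypes),
    ei = match(environment, environments),
    bi = match(cell_lab, block_cells),
    block_cell_env = match(environment[match(block_cells, cell_lab)],
                           environments),
    g = length(genotypes), e = length(environments), n = n,
    dropped = dropped)
  class(out) <- "trial_data"
  out
}

#' @export
print.trial_data <- function(x, ...) {
  cat("Multi-environment trial:", x$g, "genotypes x", x$e, "environments,",
      x$n, "records,", length(x$block_cells), "block cells\n")
  if (x$dropped) cat("(", x$dropped, "records with missing response dropped )\n")
  invisible(x)
}

#' Read a trial table from CSV
#'
#' Reads a long-format CSV and builds a [trial_data] object. Rows whose
#' response does not parse as a number are dropped and counted in the
#' object's `dropped` field.
#'
#' @param path path to a CSV file.
#' @param columns named character vector mapping the roles
#'   `genotype`, `environment`, `block`, `response` to column names in the
#'   file.
#' @return A [trial_data] object.
#' @export
read_trial_table <- function(path,
                             columns = c(genotype = "genotype",
                                         environment = "environment",
                                         block = "block",
                                         response = "response")) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  need <- c("genotype", "environment", "block", "response")
  if (!all(need %in% names(columns)))
    stop("column map must name: ", paste(need, collapse = ", "), call. = FALSE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  missing_cols <- setdiff(unname(columns[need]), names(tab))
  if (length(missing_cols))
    stop("missing column(s) in ", path, ": ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  if (nrow(tab) == 0L) stop("empty table: ", path, call. = FALSE)
  trial_data(genotype = tab[[columns[["genotype"]]]],
             environment = tab[[columns[["environment"]]]],
             block = tab[[columns[["block"]]]],
             response = suppressWarnings(as.numeric(tab[[columns[["response"]]]])))
}

#' Write a trial table to CSV
#'
#' @param data a [trial_data] object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_trial_table <- function(data, path) {
  utils::write.csv(data$records, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Build the incidence (design) matrices of the AMMI model
#'
#' Returns the three 0/1 incidence matrices of the linear-bilinear model
#' y = X1 beta + Z g + sum_k lambda_k diag(Z alpha_k) X2 gamma_k + e:
#' `X1` indexes blocks nested within environments (n x number of block
#' cells), `X2` indexes environments (n x e) and `Z` indexes genotypes
#' (n x g). Every row of each matrix has exactly one 1.
#'
#' @param data a [trial_data] object.
#' @return A list of class `design_matrices` with elements `X1`, `X2`, `Z`.
#' @export
build_designs <- function(data) {
  stopifnot(inherits(data, "trial_data"))
  inc <- function(idx, k, labs) {
    m <- matrix(0, nrow = length(idx), ncol = k, dimnames = list(NULL, labs))
    m[cbind(seq_along(idx), idx)] <- 1
    m
  }
  out <- list(X1 = inc(data$bi, length(data$block_cells), data$block_cells),
              X2 = inc(data$ei, data$e, data$environments),
              Z  = inc(data$gi, data$g, data$genotypes))
  class(out) <- "design_matrices"
  out
}

#' Double-centered cell-mean interaction matrix
#'
#' Computes the g x e matrix of cell means corrected for genotype and
#' environment means (grand mean added back), i.e. the classical
#' genotype-by-environment interaction matrix. Empty cells are imputed by
#' the additive fit (genotype mean + environment mean - grand mean), which
#' makes their interaction entry zero before centering; imputed cells are
#' flagged. This matrix is used for diagnostics, initialization and the
#' simulation truth oracle only, never by the samplers.
#'
#' @param data a [trial_data] object.
#' @return A list of class `ge_matrix` with `values` (g x e, rows sum to
#'   ~0, columns sum to ~0), `cell_means`, and `imputed` (logical g x e).
#' @export
cell_mean_interaction <- function(data) {
  stopifnot(inherits(data, "trial_data"))
  g <- data$g; e <- data$e
  sums <- matrix(0, g, e, dimnames = list(data$genotypes, data$environments))
  cnt <- matrix(0L, g, e, dimnames = dimnames(sums))
  idx <- cbind(data$gi, data$ei)
  for (r in seq_len(data$n)) {
    sums[idx[r, 1], idx[r, 2]] <- sums[idx[r, 1], idx[r, 2]] + data$records$response[r]
    cnt[idx[r, 1], idx[r, 2]] <- cnt[idx[r, 1], idx[r, 2]] + 1L
  }
  means <- sums / cnt
  imputed <- cnt == 0L
  if (any(imputed)) {
    # additive imputation from observed margins
    rm_ <- rowMeans(means, na.rm = TRUE); cm_ <- colMeans(means, na.rm = TRUE)
    gm_ <- mean(means, na.rm = TRUE)
    fill <- outer(rm_, cm_, "+") - gm_
    means[imputed] <- fill[imputed]
  }
  ge <- double_center(means)
  structure(list(values = ge, cell_means = means, imputed = imputed),
            class = "ge_matrix")
}

#' Double-center a matrix
#'
#' Subtracts row and column means and adds back the grand mean, so every
#' row and column of the result sums to zero. Idempotent.
#'
#' @param m a numeric matrix.
#' @return The centered matrix.
#' @export
double_center <- function(m) {
  sweep(sweep(m, 1, rowMeans(m)), 2, colMeans(m)) + mean(m)
}
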