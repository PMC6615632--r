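#' Construct a recombinant-line (RL) dataset
#'
#' The container consumed by the DFE samplers: one row per phenotyped
#' observation of a recombinant line, with the binary mutation matrix `M`
#' (carriage of each mutation), an optional binary two-level fixed-effect
#' matrix `F` (mating type, introgressed-region markers), an optional plate
#' index for normally distributed plate effects, an optional MA-line index
#' (merged analyses fit one overall mean per MA line), and the phenotype `y`
#' (typically maximum growth rate).
#'
#' @param y Numeric phenotype vector, length `n_b`.
#' @param M `n_b x n_m` matrix with entries 0/1; `M[i, j] = 1` when
#'   observation `i` carries mutation `j`.
#' @param F `n_b x n_f` matrix with entries 0/1, or `NULL` for no fixed
#'   effects.
#' @param plate Integer/factor plate label per observation, or `NULL` for no
#'   plate effects.
#' @param line MA-line label per observation, or `NULL` for a single line.
#' @return An object of class `rl_dataset` with elements `y`, `M`, `F`
#'   (possibly 0-column), `plate` (integer codes or `NULL`), `line`
#'   (integer codes), and the dimensions `n_b`, `n_m`, `n_f`, `n_p`,
#'   `n_lines`.
#' @export
rl_dataset <- function(y, M, F = NULL, plate = NULL, line = NULL) {
  y <- as.numeric(y)
  M <- as.matrix(M)
  n_b <- length(y)
  if (nrow(M) != n_b) stop("nrow(M) must equal length(y)")
  if (length(M) && !all(M %in% c(0, 1))) stop("M entries must be 0 or 1")
  if (is.null(F)) F <- matrix(0, n_b, 0L) else F <- as.matrix(F)
  if (nrow(F) != n_b) stop("nrow(F) must equal length(y)")
  if (length(F) && !all(F %in% c(0, 1))) stop("F entries must be 0 or 1")
  if (!is.null(plate)) {
    if (length(plate) != n_b) stop("length(plate) must equal length(y)")
    plate <- as.integer(factor(plate))
  }
  if (is.null(line)) line_idx <- rep(1L, n_b)
  else {
    if (length(line) != n_b) stop("length(line) must equal length(y)")
    line_idx <- as.integer(factor(line))
  }
  structure(
    list(y = y, M = M, F = F, plate = plate, line = line_idx,
         n_b = n_b, n_m = ncol(M), n_f = ncol(F),
         n_p = if (is.null(plate) || n_b == 0L) 0L else max(plate),
         n_lines = if (n_b == 0L) 0L else max(line_idx)),
    class = "rl_dataset")
}

#' @export
print.rl_dataset <- function(x, ...) {
  cat(sprintf(
    "RL dataset: %d observations, %d mutations, %d fixed effects, %d plates, %d MA line(s)\n",
    x$n_b, x$n_m, x$n_f, x$n_p, x$n_lines))
  invisible(x)
}

#' Write an RL dataset (plus optional simulation truth) to TSV files
#'
#' Writes three tab-separated files under `dir`: `genotypes.tsv` (one row per
#' observation, 0/1 carriage per mutation), `observations.tsv` (fixed
#' effects, plate, line, phenotype) and, when `truth` is given,
#' `truth.tsv` (simulated per-mutation effects); a `scenario.json` sidecar
#' records scenario parameters when supplied.
#'
#' @param data An [rl_dataset()].
#' @param dir Output directory (created if absent).
#' @param truth Optional data frame of simulated effects (from
#'   [simulate_rl_dataset()]).
#' @param scenario Optional [sim_scenario()] stored as JSON.
#' @return `dir`, invisibly.
#' @export
write_rl_dataset <- function(data, dir, truth = NULL, scenario = NULL) {
  stopifnot(inherits(data, "rl_dataset"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  geno <- as.data.frame(data$M)
  names(geno) <- paste0("mut_", seq_len(data$n_m))
  write.table(geno, file.path(dir, "genotypes.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  obs <- data.frame(row = seq_len(data$n_b))
  if (data$n_f > 0) {
    Fd <- as.data.frame(data$F)
    names(Fd) <- paste0("fixed_", seq_len(data$n_f))
    obs <- cbind(obs, Fd)
  }
  obs$plate <- if (is.null(data$plate)) NA_integer_ else data$plate
  obs$line <- data$line
  obs$phenotype <- data$y
  write.table(obs, file.path(dir, "observations.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  if (!is.null(truth))
    write.table(truth, file.path(dir, "truth.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  if (!is.null(scenario))
    jsonlite::write_json(unclass(scenario), file.path(dir, "scenario.json"),
                         auto_unbox = TRUE, null = "null", digits = NA)
  invisible(dir)
}

#' Read an RL dataset written by [write_rl_dataset()]
#'
#' @param dir Directory containing `genotypes.tsv` and `observations.tsv`.
#' @return An [rl_dataset()].
#' @export
read_rl_dataset <- function(dir) {
  geno <- read.delim(file.path(dir, "genotypes.tsv"), check.names = FALSE)
  obs <- read.delim(file.path(dir, "observations.tsv"), check.names = FALSE)
  fcols <- grep("^fixed_", names(obs), value = TRUE)
  F <- if (length(fcols)) as.matrix(obs[fcols]) else NULL
  plate <- if (all(is.na(obs$plate))) NULL else obs$plate
  rl_dataset(y = obs$phenotype, M = as.matrix(geno), F = F,
             plate = plate, line = obs$line)
}
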