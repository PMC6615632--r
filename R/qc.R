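#' Construct a genotype table for recombinant lines
#'
#' Holds the raw genotype calls of recombinant lines at known mutation
#' positions, prior to filtering and imputation. Calls are coded
#' `"A"` (ancestral), `"D"` (derived), `"H"` (heterozygous; suspicious in a
#' haploid and treated by downstream filters) and `"N"` (missing).
#' Marker columns (mating type, introgressed non-focal-background regions)
#' are carried separately from the mutation columns.
#'
#' @param calls Character matrix, lines x mutations, entries in
#'   `c("A", "D", "H", "N")`; row names are line ids, column names mutation
#'   ids.
#' @param chrom,pos Chromosome label and 1-based position per mutation.
#' @param mating_reaction Mating-reaction id per line (used by step-1
#'   imputation: lines from the same mating reaction with identical
#'   haplotypes are clonal copies of one meiotic product).
#' @param markers Optional character matrix, lines x markers, same coding.
#' @param annotations Optional data frame of per-mutation annotation
#'   classes (e.g. columns `type` = SNP/indel, `location` =
#'   exonic/intronic/intergenic), one row per mutation.
#' @return An object of class `genotype_table`.
#' @export
genotype_table <- function(calls, chrom, pos, mating_reaction,
                           markers = NULL, annotations = NULL) {
  calls <- as.matrix(calls)
  if (!all(calls %in% c("A", "D", "H", "N")))
    stop("calls must be one of A, D, H, N")
  n_l <- nrow(calls); n_s <- ncol(calls)
  if (length(chrom) != n_s || length(pos) != n_s)
    stop("chrom/pos must have one entry per mutation column")
  if (length(mating_reaction) != n_l)
    stop("mating_reaction must have one entry per line")
  if (is.null(rownames(calls))) rownames(calls) <- paste0("RL", seq_len(n_l))
  if (is.null(colnames(calls))) colnames(calls) <- paste0("mut", seq_len(n_s))
  if (!is.null(markers)) {
    markers <- as.matrix(markers)
    if (nrow(markers) != n_l) stop("markers must have one row per line")
    if (!all(markers %in% c("A", "D", "H", "N")))
      stop("marker calls must be one of A, D, H, N")
    if (is.null(colnames(markers)))
      colnames(markers) <- paste0("marker", seq_len(ncol(markers)))
  }
  if (!is.null(annotations) && nrow(annotations) != n_s)
    stop("annotations must have one row per mutation")
  structure(
    list(calls = calls, chrom = as.character(chrom), pos = as.numeric(pos),
         mating_reaction = as.character(mating_reaction), markers = markers,
         annotations = annotations),
    class = "genotype_table")
}

#' @export
print.genotype_table <- function(x, ...) {
  cat(sprintf("Genotype table: %d lines x %d mutations, %d marker(s)\n",
              nrow(x$calls), ncol(x$calls),
              if (is.null(x$markers)) 0L else ncol(x$markers)))
  cat(sprintf("  missing calls: %d, heterozygous calls: %d\n",
              sum(x$calls == "N"), sum(x$calls == "H")))
  invisible(x)
}

# subset a genotype_table by mutation columns / line rows
subset_table <- function(table, keep_mut = NULL, keep_line = NULL) {
  if (!is.null(keep_mut)) {
    table$calls <- table$calls[, keep_mut, drop = FALSE]
    table$chrom <- table$chrom[keep_mut]
    table$pos <- table$pos[keep_mut]
    if (!is.null(table$annotations))
      table$annotations <- table$annotations[keep_mut, , drop = FALSE]
  }
  if (!is.null(keep_line)) {
    table$calls <- table$calls[keep_line, , drop = FALSE]
    table$mating_reaction <- table$mating_reaction[keep_line]
    if (!is.null(table$markers))
      table$markers <- table$markers[keep_line, , drop = FALSE]
  }
  table
}

#' Drop mutations invariant across all lines
#'
#' A mutation column showing a single non-missing call value across every
#' line carries no segregation signal and is treated as a genotyping
#' artifact.
#'
#' @param table A [genotype_table()].
#' @return List with elements `table` (filtered) and `report`
#'   (`removed` ids, `n_removed`, `n_retained`).
#' @export
drop_invariant_mutations <- function(table) {
  stopifnot(inherits(table, "genotype_table"))
  invariant <- apply(table$calls, 2, function(col) {
    vals <- unique(col[col != "N"])
    length(vals) <= 1L
  })
  list(table = subset_table(table, keep_mut = !invariant),
       report = list(removed = colnames(table$calls)[invariant],
                     n_removed = sum(invariant),
                     n_retained = sum(!invariant)))
}

# binarize genotype calls: A -> 0, D -> 1, H/N -> NA
binarize_calls <- function(calls) {
  out <- matrix(NA_real_, nrow(calls), ncol(calls),
                dimnames = dimnames(calls))
  out[calls == "A"] <- 0
  out[calls == "D"] <- 1
  out
}

#' Drop mutations in complete linkage with a marker
#'
#' A mutation whose non-missing calls are perfectly concordant (or perfectly
#' anti-concordant) with the mating-type locus or with any
#' introgressed-region marker cannot be separated from that marker's effect
#' and is removed. Concordance is evaluated on pairwise-complete
#' observations; a mutation with no complete case against a marker is
#' retained (no evidence of linkage).
#'
#' @param table A [genotype_table()] with markers present.
#' @return List with `table` and `report` as in
#'   [drop_invariant_mutations()].
#' @export
drop_marker_linked_mutations <- function(table) {
  stopifnot(inherits(table, "genotype_table"))
  if (is.null(table$markers)) stop("no marker columns present")
  mb <- binarize_calls(table$markers)
  cb <- binarize_calls(table$calls)
  linked <- logical(ncol(cb))
  for (j in seq_len(ncol(cb))) {
    for (k in seq_len(ncol(mb))) {
      ok <- !is.na(cb[, j]) & !is.na(mb[, k])
      if (!any(ok)) next
      d <- cb[ok, j] - mb[ok, k]
      if (all(d == 0) || all(abs(d) == 1)) {
        linked[j] <- TRUE
        break
      }
    }
  }
  list(table = subset_table(table, keep_mut = !linked),
       report = list(removed = colnames(table$calls)[linked],
                     n_removed = sum(linked), n_retained = sum(!linked)))
}

#' Correct single-working-primer mutations
#'
#' For mutations where only one allele-specific primer amplified, a missing
#' call means the non-amplified allele was present; missing calls for the
#' listed mutations are set to that allele.
#'
#' @param table A [genotype_table()].
#' @param affected Data frame with columns `mutation` (id matching a column
#'   of `table$calls`) and `nonamplified_allele` (`"A"` or `"D"`).
#' @return List with `table` and `report` (`n_corrected` cells).
#' @export
correct_single_primer <- function(table, affected) {
  stopifnot(inherits(table, "genotype_table"))
  n_corrected <- 0L
  if (nrow(affected)) {
    missing_ids <- setdiff(affected$mutation, colnames(table$calls))
    if (length(missing_ids))
      stop("mutations not present in table: ",
           paste(missing_ids, collapse = ", "))
    for (i in seq_len(nrow(affected))) {
      j <- affected$mutation[i]
      allele <- affected$nonamplified_allele[i]
      if (!allele %in% c("A", "D"))
        stop("nonamplified_allele must be A or D")
      fix <- table$calls[, j] == "N"
      table$calls[fix, j] <- allele
      n_corrected <- n_corrected + sum(fix)
    }
  }
  list(table = table, report = list(n_corrected = n_corrected))
}

#' Filter lines by missingness and heterozygosity
#'
#' Removes lines for which strictly more than `max_missing` of mutation
#' calls are missing and/or strictly more than `max_het` are heterozygous.
#' Multiple heterozygous calls in a haploid suggest a mixed culture or
#' cross-contamination.
#'
#' @param table A [genotype_table()].
#' @param max_missing Maximum tolerated fraction of missing calls (default
#'   0.10).
#' @param max_het Maximum tolerated fraction of heterozygous calls (default
#'   0.05).
#' @return List with `table` and `report` (`removed` line ids,
#'   `n_removed`, `n_retained`).
#' @export
filter_lines <- function(table, max_missing = 0.10, max_het = 0.05) {
  stopifnot(inherits(table, "genotype_table"))
  if (max_missing < 0 || max_missing > 1 || max_het < 0 || max_het > 1)
    stop("thresholds must lie in [0, 1]")
  frac_n <- rowMeans(table$calls == "N")
  frac_h <- rowMeans(table$calls == "H")
  drop <- frac_n > max_missing | frac_h > max_het
  list(table = subset_table(table, keep_line = !drop),
       report = list(removed = rownames(table$calls)[drop],
                     n_removed = sum(drop), n_retained = sum(!drop)))
}

#' Squared linkage disequilibrium between two haploid sites
#'
#' Standard haploid r-squared,
#' `r2 = (p_AB - p_A p_B)^2 / (p_A (1 - p_A) p_B (1 - p_B))`, computed on
#' pairwise-complete observations. Either site monomorphic among the
#' complete cases leaves r-squared undefined (`NA`).
#'
#' @param col_a,col_b Binary (0/1) haploid call vectors, `NA` = missing.
#' @return r-squared in `[0, 1]`, or `NA` if undefined. The attribute `"D"`
#'   carries the signed disequilibrium coefficient used for imputation
#'   phasing.
#' @export
ld_r_squared <- function(col_a, col_b) {
  ok <- !is.na(col_a) & !is.na(col_b)
  a <- col_a[ok]; b <- col_b[ok]
  if (!length(a)) return(NA_real_)
  pa <- mean(a); pb <- mean(b)
  if (pa <= 0 || pa >= 1 || pb <= 0 || pb >= 1) return(NA_real_)
  D <- mean(a * b) - pa * pb
  r2 <- D^2 / (pa * (1 - pa) * pb * (1 - pb))
  structure(min(1, r2), D = D)
}

#' Impute missing genotype calls
#'
#' Two-step imputation. Step 1 uses clonality within a mating reaction: a
#' line's missing call is filled when every other line from the same mating
#' reaction that matches it at all co-called mutation sites (and is called
#' at the missing site) agrees on the call. Step 2 uses linkage
#' disequilibrium: a remaining missing call is copied from the adjacent
#' mutation (genome order, same chromosome) when their r-squared exceeds
#' `r2_threshold` (strictly), with the copy phased by the sign of D
#' (positive D: same binary state; negative D: opposite state). When both
#' neighbours qualify the higher-r-squared one is used; ties go to the
#' upstream neighbour. Imputation never alters a non-missing call, and
#' heterozygous calls are never used as donors.
#'
#' @param table A [genotype_table()].
#' @param r2_threshold LD threshold for step 2 (default 0.7; the boundary
#'   value is not used).
#' @return List with `table` and `report` (`n_missing_before`,
#'   `n_imputed_step1`, `n_imputed_step2`, `n_missing_after`).
#' @export
impute_genotypes <- function(table, r2_threshold = 0.7) {
  stopifnot(inherits(table, "genotype_table"))
  calls <- table$calls
  n_before <- sum(calls == "N")
  n_step1 <- 0L

  # step 1: identical haplotypes within a mating reaction
  for (reaction in unique(table$mating_reaction)) {
    rows <- which(table$mating_reaction == reaction)
    if (length(rows) < 2L) next
    for (l in rows) {
      miss <- which(calls[l, ] == "N")
      if (!length(miss)) next
      for (s in miss) {
        fills <- character(0)
        for (d in setdiff(rows, l)) {
          if (calls[d, s] %in% c("N", "H")) next
          co <- calls[l, ] != "N" & calls[d, ] != "N"
          co[s] <- FALSE
          if (all(calls[l, co] == calls[d, co]))
            fills <- c(fills, calls[d, s])
        }
        fills <- unique(fills)
        if (length(fills) == 1L) {
          calls[l, s] <- fills
          n_step1 <- n_step1 + 1L
        }
      }
    }
  }

  # step 2: adjacent-site LD within chromosomes
  n_step2 <- 0L
  ord <- order(table$chrom, table$pos)
  bin <- binarize_calls(calls)
  miss_cells <- which(calls == "N", arr.ind = TRUE)
  if (nrow(miss_cells)) {
    site_rank <- match(seq_len(ncol(calls)), ord)  # rank of site in order
    for (i in seq_len(nrow(miss_cells))) {
      l <- miss_cells[i, 1]; s <- miss_cells[i, 2]
      rk <- site_rank[s]
      nb_up <- if (rk > 1L) ord[rk - 1L] else NA_integer_
      nb_dn <- if (rk < length(ord)) ord[rk + 1L] else NA_integer_
      cand <- c(nb_up, nb_dn)
      cand <- cand[!is.na(cand) & table$chrom[cand] == table$chrom[s]]
      if (!length(cand)) next
      stats <- lapply(cand, function(nb) ld_r_squared(bin[, s], bin[, nb]))
      r2 <- vapply(stats, as.numeric, 0)
      usable <- !is.na(r2) & r2 > r2_threshold &
        !is.na(bin[l, cand])
      if (!any(usable)) next
      # higher r2 wins; ties to the upstream (first listed) neighbour
      pick <- which(usable)[which.max(r2[usable])]
      nb <- cand[pick]
      D <- attr(stats[[pick]], "D")
      state <- if (D >= 0) bin[l, nb] else 1 - bin[l, nb]
      calls[l, s] <- if (state == 1) "D" else "A"
      n_step2 <- n_step2 + 1L
    }
  }

  table$calls <- calls
  list(table = table,
       report = list(n_missing_before = n_before,
                     n_imputed_step1 = n_step1,
                     n_imputed_step2 = n_step2,
                     n_missing_after = sum(calls == "N")))
}

#' Summarize haplotypes among fully called lines
#'
#' A haplotype is the full vector of calls at all mutation columns;
#' identical vectors define one haplotype. Only fully called lines (no
#' missing, no heterozygous calls) enter the summary.
#'
#' @param table A [genotype_table()] (normally post-imputation).
#' @return List with `n_haplotypes`, `haplotypes` (data frame with
#'   `multiplicity` and `derived_prop`, the proportion of derived alleles in
#'   each haplotype), `mean_derived_prop`, and `n_lines_used`.
#' @export
haplotype_summary <- function(table) {
  stopifnot(inherits(table, "genotype_table"))
  complete <- rowSums(table$calls == "N" | table$calls == "H") == 0L
  calls <- table$calls[complete, , drop = FALSE]
  if (!nrow(calls))
    return(list(n_haplotypes = 0L,
                haplotypes = data.frame(multiplicity = integer(),
                                        derived_prop = numeric()),
                mean_derived_prop = NA_real_, n_lines_used = 0L))
  key <- apply(calls, 1, paste, collapse = "")
  mult <- table(key)
  first <- calls[!duplicated(key), , drop = FALSE]
  dp <- rowMeans(first == "D")
  names(dp) <- key[!duplicated(key)]
  dp <- dp[names(mult)]
  list(n_haplotypes = length(mult),
       haplotypes = data.frame(multiplicity = as.integer(mult),
                               derived_prop = as.numeric(dp),
                               row.names = NULL),
       mean_derived_prop = mean(dp),
       n_lines_used = nrow(calls))
}

#' Run the full genotype QC pipeline
#'
#' Fixed stage order: invariant-mutation drop, marker-linkage drop,
#' single-primer correction, line filter, heterozygous-to-missing recoding
#' (haploid organism), two-step imputation. Returns the cleaned table and a
#' stage-by-stage report.
#'
#' @param table A [genotype_table()].
#' @param single_primer Data frame for [correct_single_primer()] (may be
#'   empty).
#' @param max_missing,max_het Line-filter thresholds.
#' @param r2_threshold Imputation LD threshold.
#' @return List with `table` and `report` (per-stage sub-reports).
#' @export
qc_pipeline <- function(table,
                        single_primer = data.frame(mutation = character(),
                                                   nonamplified_allele = character()),
                        max_missing = 0.10, max_het = 0.05,
                        r2_threshold = 0.7) {
  report <- list()
  st <- drop_invariant_mutations(table)
  report$invariant <- st$report
  if (!is.null(st$table$markers)) {
    st <- drop_marker_linked_mutations(st$table)
    report$marker_linked <- st$report
  }
  st <- correct_single_primer(st$table,
                              single_primer[single_primer$mutation %in%
                                              colnames(st$table$calls), ,
                                            drop = FALSE])
  report$single_primer <- st$report
  st <- filter_lines(st$table, max_missing = max_missing, max_het = max_het)
  report$line_filter <- st$report
  tab <- st$table
  n_het <- sum(tab$calls == "H")
  tab$calls[tab$calls == "H"] <- "N"
  report$het_to_missing <- list(n_recoded = n_het)
  st <- impute_genotypes(tab, r2_threshold = r2_threshold)
  report$imputation <- st$report
  list(table = st$table, report = report)
}
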