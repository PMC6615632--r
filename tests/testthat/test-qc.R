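test_that("invariant mutations are dropped", {
  calls <- cbind(c("D", "D", "D", "D", "D"),   # invariant -> dropped
                 c("A", "D", "A", "D", "A"),
                 c("D", "A", "A", "A", "A"),   # one discordant -> kept
                 c("A", "N", "A", "D", "D"))
  tab <- toy_genotype_table(calls)
  res <- drop_invariant_mutations(tab)
  expect_equal(res$report$n_removed, 1)
  expect_equal(ncol(res$table$calls), 3)
  expect_equal(res$report$n_removed + res$report$n_retained, 4)

  # all-missing-but-one-value column is also invariant
  calls2 <- cbind(c("D", "N", "N"), c("A", "D", "A"))
  expect_equal(drop_invariant_mutations(toy_genotype_table(calls2))$report$n_removed, 1)
})

test_that("marker-linked mutations are dropped on perfect (anti)concordance", {
  marker <- cbind(mt = c("A", "D", "A", "D", "A", "D"))
  calls <- cbind(c("A", "D", "A", "D", "A", "D"),   # identical -> dropped
                 c("D", "A", "D", "A", "D", "A"),   # anti-concordant -> dropped
                 c("A", "D", "A", "D", "A", "A"),   # one discordant -> kept
                 c("N", "N", "N", "N", "N", "N"))   # no complete case -> kept
  tab <- toy_genotype_table(calls, markers = marker)
  res <- drop_marker_linked_mutations(tab)
  expect_equal(res$report$n_removed, 2)
  expect_equal(colnames(res$table$calls), c("mut3", "mut4"))
})

test_that("single-primer correction fills missing calls with the nonamplified allele", {
  calls <- cbind(c("D", "N", "D", "N", "N"),
                 c("A", "N", "D", "A", "D"))
  tab <- toy_genotype_table(calls)
  aff <- data.frame(mutation = "mut1", nonamplified_allele = "A")
  res <- correct_single_primer(tab, aff)
  expect_equal(res$report$n_corrected, 3)
  expect_equal(unname(res$table$calls[, 1]), c("D", "A", "D", "A", "A"))
  expect_equal(unname(res$table$calls[, 2]), unname(calls[, 2]))  # unlisted unchanged

  none <- correct_single_primer(tab, aff[0, ])
  expect_identical(none$table$calls, tab$calls)
  expect_error(correct_single_primer(
    tab, data.frame(mutation = "nope", nonamplified_allele = "A")),
    "not present")
})

test_that("line filter uses strict > thresholds", {
  n_mut <- 100
  mk_line <- function(n_miss, n_het) {
    c(rep("N", n_miss), rep("H", n_het), rep("A", n_mut - n_miss - n_het))
  }
  calls <- rbind(mk_line(11, 0),   # 11% missing  -> removed
                 mk_line(10, 5),   # exactly at both thresholds -> retained
                 mk_line(0, 6),    # 6% heterozygous -> removed
                 mk_line(0, 0))    # clean -> retained
  calls[, n_mut] <- c("D", "D", "D", "A")  # keep table from being invariant
  tab <- toy_genotype_table(calls)
  res <- filter_lines(tab)
  expect_equal(res$report$n_removed, 2)
  expect_equal(rownames(res$table$calls), c("RL2", "RL4"))
})

test_that("LD r-squared matches the 2x2 haplotype-table formula", {
  a <- c(rep(1, 50), rep(0, 50))
  expect_equal(as.numeric(ld_r_squared(a, a)), 1)

  # balanced independent table: D = 0
  b <- rep(c(1, 0), 50)
  expect_equal(as.numeric(ld_r_squared(a, b)), 0)

  # counts AB=40, Ab=10, aB=10, ab=40 -> r2 = 0.36
  x <- c(rep(1, 40), rep(1, 10), rep(0, 10), rep(0, 40))
  z <- c(rep(1, 40), rep(0, 10), rep(1, 10), rep(0, 40))
  expect_equal(as.numeric(ld_r_squared(x, z)), 0.36, tolerance = 1e-12)

  # symmetry and allele-label-swap invariance on random pairs
  set.seed(5)
  for (i in 1:20) {
    u <- rbinom(60, 1, 0.5)
    w <- rbinom(60, 1, 0.5)
    u[sample(60, 5)] <- NA
    r_uw <- as.numeric(ld_r_squared(u, w))
    expect_equal(r_uw, as.numeric(ld_r_squared(w, u)))
    expect_equal(r_uw, as.numeric(ld_r_squared(1 - u, w)))
  }

  # monomorphic column undefined
  expect_true(is.na(ld_r_squared(rep(1, 10), rbinom(10, 1, 0.5))))
})

test_that("imputation fills by clonal haplotype match then by adjacent-site LD", {
  # step 1: same mating reaction, identical at co-called sites
  calls <- rbind(c("A", "D", "N", "A"),
                 c("A", "D", "D", "A"),    # clonal donor
                 c("D", "A", "A", "D"))
  tab <- toy_genotype_table(calls, reaction = c("r1", "r1", "r2"))
  res <- impute_genotypes(tab)
  expect_equal(res$report$n_imputed_step1, 1)
  expect_equal(unname(res$table$calls[1, 3]), "D")
  expect_equal(res$report$n_missing_after, 0)

  # step 2 positive-D copy: adjacent columns in perfect LD (r2 = 1)
  coupled <- rbind(c("A", "A"), c("A", "A"), c("D", "D"), c("D", "D"),
                   c("A", "A"), c("D", "N"))
  tab2 <- toy_genotype_table(coupled, reaction = paste0("r", 1:6))
  res2 <- impute_genotypes(tab2)
  expect_equal(res2$report$n_imputed_step2, 1)
  expect_equal(unname(res2$table$calls[6, 2]), "D")

  # step 2 negative-D copy: perfect anti-coupling imputes the opposite state
  anti <- rbind(c("A", "D"), c("A", "D"), c("D", "A"), c("D", "A"),
                c("A", "D"), c("D", "N"))
  tab3 <- toy_genotype_table(anti, reaction = paste0("r", 1:6))
  res3 <- impute_genotypes(tab3)
  expect_equal(unname(res3$table$calls[6, 2]), "A")

  # r2 exactly at the threshold is not used (strict > 0.7)
  half <- rbind(c("A", "A"), c("A", "A"), c("D", "D"), c("D", "D"),
                c("A", "A"), c("D", "D"), c("A", "D"), c("D", "A"),
                c("A", "N"))
  tab4 <- toy_genotype_table(half, reaction = paste0("r", 1:9))
  r2 <- as.numeric(ld_r_squared(binarize_test(half[1:8, 1]),
                                binarize_test(half[1:8, 2])))
  res4 <- impute_genotypes(tab4, r2_threshold = r2)
  expect_equal(res4$report$n_imputed_step2, 0)
  res4b <- impute_genotypes(tab4, r2_threshold = r2 - 1e-9)
  expect_equal(res4b$report$n_imputed_step2, 1)

  # imputation never alters a non-missing call
  pre <- tab2$calls
  post <- res2$table$calls
  expect_true(all(post[pre != "N"] == pre[pre != "N"]))

  # no missing -> unchanged
  res5 <- impute_genotypes(toy_genotype_table(coupled[1:5, ]))
  expect_equal(res5$report$n_imputed_step1 + res5$report$n_imputed_step2, 0)

  # no imputation across chromosomes
  cross <- rbind(c("A", "A"), c("A", "A"), c("D", "D"), c("D", "D"),
                 c("A", "A"), c("D", "N"))
  tabx <- toy_genotype_table(cross, chrom = c("chr1", "chr2"),
                             reaction = paste0("r", 1:6))
  resx <- impute_genotypes(tabx)
  expect_equal(resx$report$n_imputed_step2, 0)
})

test_that("haplotype summary keys on the full call vector", {
  same <- rbind(c("A", "D"), c("A", "D"), c("A", "D"))
  hs <- haplotype_summary(toy_genotype_table(same))
  expect_equal(hs$n_haplotypes, 1)

  mix <- rbind(c("A", "D"), c("A", "D"), c("D", "D"))
  hs2 <- haplotype_summary(toy_genotype_table(mix))
  expect_equal(hs2$n_haplotypes, 2)
  expect_setequal(hs2$haplotypes$multiplicity, c(2, 1))
  expect_setequal(hs2$haplotypes$derived_prop, c(0.5, 1))
  expect_equal(hs2$mean_derived_prop, 0.75)

  # incompletely called lines are excluded
  withN <- rbind(c("A", "N"), c("A", "D"))
  expect_equal(haplotype_summary(toy_genotype_table(withN))$n_lines_used, 1)
})

test_that("the QC pipeline reconciles counts across stages", {
  set.seed(11)
  n_l <- 30
  base <- matrix(sample(c("A", "D"), n_l * 6, replace = TRUE), n_l, 6)
  base[, 3] <- "D"                             # invariant
  marker <- cbind(mt = base[, 4])              # column 4 marker-linked
  base[sample(n_l, 4), 5] <- "N"
  base[2, ] <- "N"                             # line killed by missingness
  tab <- toy_genotype_table(base, markers = marker,
                            reaction = rep(paste0("r", 1:5), 6))
  out <- qc_pipeline(tab)
  rep <- out$report
  expect_equal(rep$invariant$n_removed + rep$invariant$n_retained, 6)
  expect_gte(rep$invariant$n_removed, 1)
  expect_gte(rep$marker_linked$n_removed, 1)
  expect_gte(rep$line_filter$n_removed, 1)
  expect_equal(nrow(out$table$calls), rep$line_filter$n_retained)
  expect_lte(rep$imputation$n_missing_after, rep$imputation$n_missing_before)
  expect_equal(rep$imputation$n_missing_before -
                 rep$imputation$n_imputed_step1 -
                 rep$imputation$n_imputed_step2,
               rep$imputation$n_missing_after)
})
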