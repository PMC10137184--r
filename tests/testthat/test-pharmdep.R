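make_panel <- function(values, drug = "d1", source = "S1", measure = "ln_IC50") {
  tibble::tibble(cell_line = sprintf("L%02d", seq_along(values)),
                 drug = drug, measure = measure, value = values,
                 source = source)
}

test_that("tertile categorization splits ordered lines and excludes ties", {
  cat9 <- categorize_lines(make_panel(1:9))
  expect_identical(cat9$category[order(cat9$value)],
                   rep(c("sensitive", "excluded", "resistant"), each = 3))
  expect_true(all(categorize_lines(make_panel(rep(2, 9)))$category == "excluded"))
  expect_warning(cat5 <- categorize_lines(make_panel(1:5)), "< 6")
  expect_true(all(cat5$category == "excluded"))
  thr <- categorize_lines(make_panel(c(-2, 0, 2)), method = "threshold")
  expect_identical(thr$category, c("sensitive", "excluded", "resistant"))
})

test_that("gene-drug calls follow the direction of significant differences", {
  set.seed(1)
  pan <- categorize_lines(make_panel(1:12))
  sens_lines <- pan$cell_line[pan$category == "sensitive"]
  res_lines <- pan$cell_line[pan$category == "resistant"]
  x <- matrix(rnorm(3 * 12, 5, 0.3), nrow = 3,
              dimnames = list(c("up_in_sens", "up_in_res", "null"),
                              sprintf("L%02d", 1:12)))
  x["up_in_sens", sens_lines] <- x["up_in_sens", sens_lines] + 3
  x["up_in_res", res_lines] <- x["up_in_res", res_lines] + 3
  calls <- gene_drug_call(x, pan, "d1")
  expect_identical(calls$call[calls$id == "up_in_sens"], "sensitive")
  expect_identical(calls$call[calls$id == "up_in_res"], "resistant")
  expect_identical(calls$call[calls$id == "null"], "neutral")
  expect_error(gene_drug_call(x, pan, "ghost"), "not in panel")
})

test_that("conflicting strata veto the per-drug call", {
  set.seed(2)
  p1 <- make_panel(1:12, source = "S1")
  p2 <- make_panel(12:1, source = "S2")   # reversed ordering
  pan <- categorize_lines(dplyr::bind_rows(p1, p2))
  x <- matrix(rnorm(12, 5, 0.3), nrow = 1,
              dimnames = list("g", sprintf("L%02d", 1:12)))
  x["g", sprintf("L%02d", 1:4)] <- x["g", sprintf("L%02d", 1:4)] + 3
  calls <- gene_drug_call(x, pan, "d1")
  expect_identical(calls$call, "neutral")
  expect_identical(calls$flag, "conflicting_strata")
})

test_that("pan calls respect layer concordance and the sensitive-call floor", {
  drugs <- sprintf("drug%02d", 1:21)
  mk_calls <- function(id, layer, calls) {
    tibble::tibble(id = id, drug = drugs, layer = layer, call = calls)
  }
  # DGKE pattern: sensitive to one drug, neutral elsewhere, both layers
  dgke <- dplyr::bind_rows(
    mk_calls("DGKE", "mRNA", c("sensitive", rep("neutral", 20))),
    mk_calls("DGKE", "protein", c("sensitive", rep("neutral", 20))))
  expect_identical(pan_call(dgke)$call, "pansensitive")
  # WDR47 pattern: resistant to three drugs, never sensitive
  wdr <- dplyr::bind_rows(
    mk_calls("WDR47", "mRNA", c(rep("resistant", 3), rep("neutral", 18))),
    mk_calls("WDR47", "protein", c(rep("resistant", 3), rep("neutral", 18))))
  expect_identical(pan_call(wdr)$call, "panresistant")
  # neutral everywhere: the vacuous-call guard
  neut <- dplyr::bind_rows(mk_calls("N1", "mRNA", rep("neutral", 21)),
                           mk_calls("N1", "protein", rep("neutral", 21)))
  expect_identical(pan_call(neut)$call, "neither")
  # discordant layers
  disc <- dplyr::bind_rows(
    mk_calls("D1", "mRNA", c("sensitive", rep("neutral", 20))),
    mk_calls("D1", "protein", c("resistant", rep("neutral", 20))))
  got <- pan_call(disc)
  expect_identical(got$call, "neither")
  expect_identical(got$flag, "discordant_layers")
  # missing protein layer
  mono <- mk_calls("M1", "mRNA", c("sensitive", rep("neutral", 20)))
  got2 <- pan_call(mono)
  expect_identical(got2$call, "neither")
  expect_identical(got2$flag, "missing_layer")
  # miRNAs evaluated on their own layer alone
  mir <- mk_calls("hsa-miR-x", "miRNA", c("sensitive", rep("neutral", 20)))
  expect_identical(pan_call(mir, layers_required = "miRNA")$call, "pansensitive")
})

test_that("pan calls agree with the enumeration oracle and are exclusive", {
  set.seed(42)
  n_vec <- 2000
  states <- c("sensitive", "resistant", "neutral")
  boundary <- list(rep("neutral", 21), rep("sensitive", 21), rep("resistant", 21),
                   c("sensitive", rep("neutral", 20)),
                   c("resistant", rep("neutral", 20)),
                   c("sensitive", "resistant", rep("neutral", 19)))
  vectors <- c(boundary, lapply(seq_len(n_vec), function(i)
    sample(states, 21, replace = TRUE, prob = c(0.1, 0.1, 0.8))))
  calls <- dplyr::bind_rows(lapply(seq_along(vectors), function(i) {
    tibble::tibble(id = sprintf("v%05d", i), drug = sprintf("drug%02d", 1:21),
                   layer = "miRNA", call = vectors[[i]])
  }))
  got <- pan_call(calls, layers_required = "miRNA")
  got <- got[order(got$id), ]
  oracle <- vapply(vectors, pan_oracle, character(1))
  expect_identical(got$call, oracle)
  # removing a drug never demotes pansensitive to panresistant
  for (i in which(oracle == "pansensitive")[1:50]) {
    reduced <- pan_oracle(vectors[[i]][-1])
    expect_true(reduced %in% c("pansensitive", "neither"))
  }
})

test_that("radiotherapy grouping uses open intervals and the stage filter", {
  set.seed(6)
  n <- 30
  md <- tibble::tibble(
    sample_id = sprintf("P%02d", 1:n),
    stage = rep(c("III", "IV", "I"), each = 10),
    radiotherapy = rep(c(TRUE, TRUE, TRUE), each = 10),
    time_months = c(rep(70, 5), rep(10, 5),      # stage III: long / short
                    rep(65, 3), rep(15, 5), 58, 20,  # stage IV incl. boundaries
                    rep(100, 10)),               # stage I: filtered out
    event = TRUE)
  x <- matrix(rnorm(2 * n, 5, 0.3), nrow = 2,
              dimnames = list(c("rt_gene", "flat"), md$sample_id))
  long_ids <- md$sample_id[md$stage %in% c("III", "IV") & md$time_months > 58]
  x["rt_gene", long_ids] <- x["rt_gene", long_ids] + 3
  got <- radiotherapy_call(x, md)
  expect_identical(got$call[got$gene_id == "rt_gene"], "rt_sensitive")
  expect_identical(got$call[got$gene_id == "flat"], "neutral")
  # boundary patients (58 and 20 months) belong to neither group
  expect_equal(unique(got$n_long), 8)
  expect_equal(unique(got$n_short), 10)
  md_small <- md[md$time_months < 58, ]
  expect_error(radiotherapy_call(x, md_small), ">= 2")
})

test_that("dependency normalization pins anchor medians exactly", {
  raw <- rbind(E1 = c(-2.2, -1.4), E2 = c(-2.0, -1.0), E3 = c(-1.8, -0.6),
               N1 = c(0.8, 0.4), N2 = c(1.0, 0.5), N3 = c(1.2, 0.6),
               G1 = c(-0.5, 0.2))
  colnames(raw) <- c("lineA", "lineB")
  screen <- list(assay = "CRISPR", raw = raw,
                 essential_ids = c("E1", "E2", "E3"),
                 nonessential_ids = c("N1", "N2", "N3"))
  norm <- normalize_dependency(screen)$normalized
  expect_lt(max(abs(apply(norm[c("E1", "E2", "E3"), ], 2, median) + 1)), 1e-9)
  expect_lt(max(abs(apply(norm[c("N1", "N2", "N3"), ], 2, median))), 1e-9)
  # worked affine example: m_ess = -2, m_non = 1 in lineA
  expect_equal(norm["N2", "lineA"], 0)
  expect_equal(norm["E2", "lineA"], -1)
  expect_equal(norm["G1", "lineA"], -0.5)   # (-0.5 - 1) / (1 - (-2))
  # exactly at the threshold is NOT significant under strict <
  prof <- proliferation_profile(list(assay = "CRISPR", normalized = norm,
                                     essential_ids = screen$essential_ids,
                                     nonessential_ids = screen$nonessential_ids),
                                genes = "G1")
  expect_equal(prof$frac_crispr, 0)   # lineA sits exactly at -0.5
  # degenerate line errors with its name
  raw_bad <- raw; raw_bad[1:6, 2] <- 0
  expect_error(normalize_dependency(list(assay = "CRISPR", raw = raw_bad,
                                         essential_ids = c("E1", "E2", "E3"),
                                         nonessential_ids = c("N1", "N2", "N3"))),
               "lineB")
})

test_that("proliferation classes follow the majority rules", {
  mk_screen <- function(frac, n_lines = 10) {
    norm <- matrix(0, nrow = 1, ncol = n_lines,
                   dimnames = list("G", sprintf("L%02d", 1:n_lines)))
    norm[1, seq_len(round(frac * n_lines))] <- -1
    list(assay = "CRISPR", normalized = norm, essential_ids = character(),
         nonessential_ids = character())
  }
  prof <- function(f1, f2) {
    proliferation_profile(mk_screen(f1), mk_screen(f2), genes = "G")$class
  }
  expect_identical(prof(0.8, 0.6), "both_major")
  expect_identical(prof(0.8, 0.2), "either_major")
  expect_identical(prof(0, 0), "none_significant")
  expect_identical(prof(0.3, 0.1), "other")
  single <- proliferation_profile(mk_screen(0.8), NULL, genes = "G")
  expect_identical(single$class, "either_major")
  expect_identical(single$flag, "single_assay")
})

test_that("responder genes require concordant two-layer significance", {
  set.seed(9)
  pan <- categorize_lines(make_panel(1:12))
  sens <- pan$cell_line[pan$category == "sensitive"]
  res <- pan$cell_line[pan$category == "resistant"]
  mk_expr <- function(shift_gene, shift_lines, shift) {
    x <- matrix(rnorm(3 * 12, 5, 0.3), nrow = 3,
                dimnames = list(c("conc", "mrna_only", "opposed"),
                                sprintf("L%02d", 1:12)))
    x[shift_gene, shift_lines] <- x[shift_gene, shift_lines] + shift
    x
  }
  mrna <- mk_expr("conc", sens, 3)
  mrna["mrna_only", sens] <- mrna["mrna_only", sens] + 3
  mrna["opposed", sens] <- mrna["opposed", sens] + 3
  prot <- mk_expr("conc", sens, 3)
  prot["opposed", res] <- prot["opposed", res] + 3
  got <- responder_genes(mrna, prot, pan, "d1")
  expect_identical(got$gene_id, "conc")
  expect_identical(got$direction, "sensitive_associated")
})
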