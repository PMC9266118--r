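test_that("differentiation scores reproduce the printed ranges and gap rule", {
  expect_equal(corneal_diff_score(c(0, 10, 200)), c(1L, 2L, 3L))
  expect_equal(corneal_diff_score(3.0), 2L)    # 3.0 > sqrt(0.9 * 5.5)
  expect_equal(corneal_diff_score(2.0), 1L)    # below the geometric midpoint
  expect_equal(corneal_diff_score(61), 3L)     # above sqrt(20 * 180) = 60
  expect_equal(conjunctival_diff_score(c(0.1, 15)), c(1L, 2L))
  expect_equal(conjunctival_diff_score(2.0), 1L)  # 2.0 < sqrt(0.8 * 9)
  expect_equal(conjunctival_diff_score(3.0), 2L)
  expect_error(corneal_diff_score(-1), "non-negative")
  expect_error(corneal_diff_score(NaN), "finite")
  expect_error(corneal_diff_score(2.0, gap_mode = "strict"), "gap")
  expect_error(conjunctival_diff_score(5, gap_mode = "strict"), "gap")
})

test_that("scoring is a total monotone function on the non-negative reals", {
  set.seed(6)
  x <- sort(c(0, runif(200, 0, 400)))
  sc <- corneal_diff_score(x)
  expect_true(all(sc %in% 1:3))
  expect_true(all(diff(sc) >= 0))
  sj <- conjunctival_diff_score(sort(runif(200, 0, 30)))
  expect_true(all(sj %in% 1:2))
  expect_true(all(diff(sj) >= 0))
})

test_that("epithelial segregation keys on any strong cytokeratin", {
  ml <- rbind(epi = c(Krt14 = 50, Col1a1 = 0, Krt12 = 0, Trdc = 0),
              strom = c(Krt14 = 0, Col1a1 = 30, Krt12 = 0, Trdc = 0),
              weak = c(Krt14 = 0.5, Col1a1 = 0, Krt12 = 0.2, Trdc = 0))
  pr <- manual_profiles(rownames(ml), rep("unwounded", 3), c(10, 10, 10), ml)
  flags <- segregate_epithelial(pr, threshold = 1)
  expect_equal(unname(flags), c(TRUE, FALSE, FALSE))
})

test_that("non-epithelial typing follows the winning panel, ties unresolved", {
  genes <- c("Col1a1", "Col1a2", "Dcn", "Cd34", "Trdc", "Cd3g", "Trbc1",
             "Cxcl2", "Ccl4", "Cd14")
  base <- matrix(0.1, 4, length(genes), dimnames = list(NULL, genes))
  base[2, c("Trdc", "Cd3g", "Trbc1")] <- 20
  base[3, c("Cxcl2", "Ccl4", "Cd14")] <- 20
  base[1, c("Col1a1", "Col1a2", "Dcn")] <- 20
  pr <- manual_profiles(c("s", "t", "m", "tie"), rep("wounded", 4),
                        rep(10, 4), base)
  ty <- type_non_epithelial(pr)
  expect_equal(unname(ty[1:3]), c("stromal", "t_cell", "macrophage"))
  expect_equal(unname(ty[4]), "unresolved")
})

test_that("epithelial percentages are per-condition fractions summing to one", {
  ml <- matrix(1, 4, 2, dimnames = list(NULL, c("Krt14", "Krt12")))
  ml[, 1] <- 30
  pr <- manual_profiles(c("A", "B", "A2", "B2"),
                        c("unwounded", "unwounded", "wounded", "wounded"),
                        c(20, 80, 50, 150), ml)
  flags <- setNames(rep(TRUE, 4), rownames(pr$mean_linear))
  ct <- data.frame(name = c("A+A2", "B+B2"), presence = "shared",
                   member_unwounded = c("A", "B"),
                   member_wounded = c("A2", "B2"), branch = "B1")
  pct <- epithelial_percentages(pr, flags, ct)
  expect_equal(pct$fraction[pct$name == "A+A2" & pct$condition == "unwounded"],
               0.2)
  expect_equal(pct$fraction[pct$name == "B+B2" & pct$condition == "unwounded"],
               0.8)
  expect_equal(pct$fraction[pct$name == "A+A2" & pct$condition == "wounded"],
               0.25)
  for (cond in c("unwounded", "wounded")) {
    expect_equal(sum(pct$fraction[pct$condition == cond]), 1)
  }
})

test_that("proliferation flag needs a clear panel z-score excess", {
  genes <- c("Mki67", paste0("Mcm", 2:7), "Krt14")
  M <- matrix(0.3, 10, length(genes), dimnames = list(NULL, genes))
  M[2, seq_len(7)] <- 5
  pr <- manual_profiles(paste0("k", 1:10), rep("unwounded", 10), rep(10, 10),
                        expm1(M), M)
  fl <- flag_proliferative(pr)
  expect_equal(unname(fl), c(FALSE, TRUE, rep(FALSE, 8)))

  flat <- manual_profiles(paste0("k", 1:10), rep("unwounded", 10), rep(10, 10),
                          expm1(M * 0 + 0.3), M * 0 + 0.3)
  expect_false(any(flag_proliferative(flat)))
  two <- manual_profiles(c("a", "b"), rep("unwounded", 2), c(5, 5),
                         M[1:2, ])
  expect_error(flag_proliferative(two), "at least 3")
})

# build a complete small designation scenario:
# trajectory branch B3 holds two shared LSC candidates and an LPC;
# B2 holds a differentiating type and a conjunctival type; B1 is inert
designation_fixture <- function(pct_u_lsc2 = 0.20, pct_w_lsc2 = 0.11) {
  genes <- c("Krt12", "Krt13", "Krt14", "Krt15",
             "Mki67", paste0("Mcm", 2:7))
  rows <- list(
    LSC1u = c(0.3, 0.2, 30, 30), LSC1w = c(0.3, 0.2, 30, 30),
    LSC2u = c(0.3, 0.2, 30, 30), LSC2w = c(0.3, 0.2, 30, 30),
    LPCu  = c(12, 0.2, 15, 15),  LPCw  = c(12, 0.2, 15, 15),
    DIFu  = c(250, 0.2, 2, 2),   DIFw  = c(250, 0.2, 2, 2),
    CJu   = c(12, 15, 2, 2),     CJw   = c(12, 15, 2, 2),
    UNKu  = c(0.3, 0.2, 8, 8),   UNKw  = c(0.3, 0.2, 8, 8))
  ml <- do.call(rbind, rows)
  ml <- cbind(ml, matrix(0.3, nrow(ml), 7))
  colnames(ml) <- genes
  ml["LPCu", "Mki67"] <- 8
  ml["LPCu", paste0("Mcm", 2:7)] <- 6
  conds <- rep(c("unwounded", "wounded"), 6)
  ids <- names(rows)
  # unwounded epithelial counts: LSC1 .18, LSC2 pct_u, rest split
  n_u <- c(0.18, pct_u_lsc2, 0.22, 0.2, 0.1, 0.3 - pct_u_lsc2) * 1000
  n_w <- c(0.22, pct_w_lsc2, 0.25, 0.2, 0.12, 0.21 - pct_w_lsc2) * 1000
  n <- as.vector(rbind(n_u, n_w))
  pr <- manual_profiles(ids, conds, n, ml)
  ct <- data.frame(
    name = c("LSC1", "LSC2", "LPC", "DIF", "CJ", "UNK"),
    presence = "shared",
    member_unwounded = c("LSC1u", "LSC2u", "LPCu", "DIFu", "CJu", "UNKu"),
    member_wounded = c("LSC1w", "LSC2w", "LPCw", "DIFw", "CJw", "UNKw"),
    branch = c("B3", "B3", "B3", "B2", "B2", "B1"))
  flags <- setNames(rep(TRUE, 12), rownames(pr$mean_linear))
  list(profiles = pr, cell_types = ct, flags = flags)
}

test_that("designation separates active and quiescent LSCs by abundance shift", {
  fx <- designation_fixture(pct_u_lsc2 = 0.20, pct_w_lsc2 = 0.11)
  d <- designate(fx$cell_types, fx$profiles, fx$flags)
  lab <- setNames(d$label, d$cell_type)
  expect_equal(lab[["LSC1"]], "putative_quiescent_LSC")  # 0.18 -> 0.22
  expect_equal(lab[["LSC2"]], "putative_active_LSC")     # 0.20 -> 0.11
  expect_equal(lab[["LPC"]], "putative_LPC")
  expect_equal(lab[["DIF"]], "putative_differentiating_LPC")
  expect_equal(lab[["CJ"]], "putative_CjPC")
  expect_equal(lab[["UNK"]], "unknown_origin_SPC")
  expect_true(d$proliferative[d$cell_type == "LPC"])
  expect_equal(sum(d$proliferative), 1)
  # every type gets exactly one label
  expect_false(any(is.na(d$label)))
  expect_equal(d$abundance_change[d$cell_type == "LSC2"],
               (0.11 - 0.20) / 0.20)
})

test_that("an LSC without a clear decrease stays quiescent", {
  fx <- designation_fixture(pct_u_lsc2 = 0.15, pct_w_lsc2 = 0.15)
  d <- designate(fx$cell_types, fx$profiles, fx$flags)
  expect_equal(d$label[d$cell_type == "LSC2"], "putative_quiescent_LSC")
})

test_that("without a trajectory branch the LSC labels are withheld", {
  fx <- designation_fixture()
  # remove the partially differentiated types from B3 so no branch qualifies
  ct <- fx$cell_types
  ct$branch[ct$name == "LPC"] <- "B2"
  expect_warning(d <- designate(ct, fx$profiles, fx$flags),
                 "no trajectory")
  expect_false(any(grepl("LSC", d$label)))
})
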