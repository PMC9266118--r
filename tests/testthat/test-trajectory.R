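test_that("three-profile dendrogram matches the brute-force oracle", {
  set.seed(20)
  M <- rbind(a = abs(rnorm(40, 1, 0.5)),
             b = abs(rnorm(40, 1, 0.5)),
             c = abs(rnorm(40, 1, 0.5)))
  M["b", ] <- M["a", ] + rnorm(40, 0, 0.05)  # b is nearly a
  colnames(M) <- paste0("g", 1:40)
  pr <- manual_profiles(c("a", "b", "c"), rep("unwounded", 3),
                        c(10, 10, 10), mean_linear = expm1(M), mean_expr = M)
  d <- build_joint_dendrogram(pr)
  # oracle: with 3 leaves the only decision is the first merge = argmin pair
  dm <- 1 - cor(t(M))
  pairs <- list(c("a", "b"), c("a", "c"), c("b", "c"))
  dvals <- sapply(pairs, function(p) dm[p[1], p[2]])
  expected_cherry <- sort(paste(pairs[[which.min(dvals)]],
                                "unwounded", sep = "|"))
  expect_equal(extract_cherries(d), list(expected_cherry))
  # UPGMA root height = mean distance from the cherry to the outgroup
  out <- setdiff(c("a", "b", "c"), pairs[[which.min(dvals)]])
  expect_equal(max(d$hclust$height),
               mean(dm[out, pairs[[which.min(dvals)]]]))
})

test_that("identical profiles merge at height zero; order does not matter", {
  M <- rbind(x = c(1, 2, 3, 4), y = c(1, 2, 3, 4), z = c(4, 3, 2, 1))
  colnames(M) <- paste0("g", 1:4)
  pr <- manual_profiles(c("x", "y", "z"), rep("unwounded", 3), c(5, 5, 5),
                        mean_linear = expm1(M), mean_expr = M)
  d <- build_joint_dendrogram(pr)
  expect_equal(min(d$hclust$height), 0)

  perm <- manual_profiles(c("z", "x", "y"), rep("unwounded", 3), c(5, 5, 5),
                          mean_linear = expm1(M[c(3, 1, 2), ]),
                          mean_expr = M[c(3, 1, 2), ])
  expect_identical(ape::write.tree(build_joint_dendrogram(perm)$phylo),
                   ape::write.tree(d$phylo))
})

test_that("cherry extraction matches enumeration on known topologies", {
  two <- ape::read.tree(text = "(a:1,b:1);")
  expect_equal(extract_cherries(two), list(c("a", "b")))
  caterpillar <- ape::read.tree(text = "(((a:1,b:1):1,c:2):1,d:3);")
  expect_equal(extract_cherries(caterpillar), list(c("a", "b")))
  balanced <- ape::read.tree(text = "((a:1,b:1):1,(c:1,d:1):1);")
  expect_equal(extract_cherries(balanced), list(c("a", "b"), c("c", "d")))
})

test_that("cherries survive a Newick round trip", {
  set.seed(33)
  for (i in 1:20) {
    phy <- ape::rtree(sample(4:15, 1))
    f <- withr::local_tempfile(fileext = ".nwk")
    write_dendrogram(phy, f)
    expect_equal(extract_cherries(read_dendrogram(f)),
                 extract_cherries(phy))
  }
})

test_that("the 16-leaf fixture yields 11 cell types: 5 shared, 3 + 3 exclusive", {
  d <- read_dendrogram(fixture_tree_path())
  ct <- assign_cell_types(d, d$phylo$tip.label)
  expect_equal(nrow(ct), 11)
  expect_equal(sum(ct$presence == "shared"), 5)
  expect_equal(sum(ct$presence == "unwounded_only"), 3)
  expect_equal(sum(ct$presence == "wounded_only"), 3)
  shared <- ct[ct$presence == "shared", ]
  expect_setequal(paste(shared$member_unwounded, shared$member_wounded),
                  c("EC7 EC15", "EC8 EC16", "EC2 EC9", "EC3 EC10",
                    "EC4 EC11"))
})

test_that("same-condition cherries are not merged and singletons stand alone", {
  same <- ape::read.tree(text = "(A|unwounded:1,B|unwounded:1);")
  ct <- assign_cell_types(same, same$tip.label)
  expect_equal(nrow(ct), 2)
  expect_true(all(ct$presence == "unwounded_only"))

  one <- ape::read.tree(text = "(A|wounded:1,B|unwounded:1);")
  ct1 <- assign_cell_types(one, "A|wounded")  # only one epithelial leaf
  expect_equal(nrow(ct1), 1)
  expect_equal(ct1$presence, "wounded_only")
})

test_that("cell-type count identity holds on random condition-labelled trees", {
  set.seed(77)
  for (i in 1:1000) {
    n <- sample(3:24, 1)
    phy <- ape::rtree(n)
    conds <- sample(c("unwounded", "wounded"), n, replace = TRUE)
    phy$tip.label <- paste(paste0("C", seq_len(n)), conds, sep = "|")
    epi <- sample(phy$tip.label, sample(seq_len(n), 1))
    ct <- assign_cell_types(phy, epi)
    cherries <- extract_cherries(phy)
    cross <- sum(vapply(cherries, function(ch) {
      all(ch %in% epi) &&
        length(unique(sub("^.*\\|", "", ch))) == 2
    }, NA))
    expect_equal(nrow(ct), length(epi) - cross)
    expect_equal(sum(ct$presence == "shared"), cross)
  }
})

test_that("branch extraction cuts the epithelial subtree at the top merges", {
  d <- read_dendrogram(fixture_tree_path())
  leaves <- d$phylo$tip.label
  b3 <- extract_branches(d, leaves, k = 3)
  grp <- split(names(b3), b3)
  expect_equal(length(grp), 3)
  expect_setequal(grp[[b3[["EC1|unwounded"]]]],
                  c("EC1|unwounded", "EC2|unwounded", "EC9|wounded"))
  expect_setequal(grp[[b3[["EC3|unwounded"]]]],
                  c("EC3|unwounded", "EC10|wounded", "EC4|unwounded",
                    "EC11|wounded"))
  expect_equal(length(grp[[b3[["EC7|unwounded"]]]]), 9)

  expect_equal(length(unique(extract_branches(d, leaves, k = 1))), 1)
  singletons <- extract_branches(d, leaves, k = length(leaves))
  expect_equal(length(unique(singletons)), length(leaves))
  expect_error(extract_branches(d, leaves, k = 0), "between")

  # restriction: cutting only a subset of leaves
  sub_b <- extract_branches(d, c("EC1|unwounded", "EC2|unwounded",
                                 "EC9|wounded", "EC7|unwounded"), k = 2)
  expect_equal(unname(sub_b[["EC7|unwounded"]] !=
                        sub_b[["EC1|unwounded"]]), TRUE)
  expect_equal(sub_b[["EC1|unwounded"]], sub_b[["EC2|unwounded"]])
})
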