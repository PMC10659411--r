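test_that("poisson distances match closed forms and hand counts", {
  m <- new_msa(c("a", "b"), c("MKVL", "MKVL"))
  expect_equal(poisson_distance(m)["a", "b"], 0)

  # p = 0.5 -> -ln(0.5)
  m <- new_msa(c("a", "b"), c("MKVL", "MKAA"))
  expect_equal(poisson_distance(m)["a", "b"], -log(0.5))

  # 3-row toy with gaps: pairwise-complete columns only
  m <- new_msa(c("a", "b", "c"), c("MKVLQ", "MKAL-", "M-VAQ"),
               check_all_gap = FALSE)
  D <- poisson_distance(m)
  expect_equal(D["a", "b"], -log(1 - 1 / 4))  # 4 shared columns, 1 mismatch
  expect_equal(D["a", "c"], -log(1 - 1 / 4))  # cols 1,3,4,5; mismatch at 4
  expect_equal(D["b", "c"], -log(1 - 2 / 3))  # cols 1,3,4
  expect_true(isSymmetric(D))

  # saturation: disjoint rows hit the 0.95 cap
  m <- new_msa(c("a", "b"), c(strrep("W", 40), strrep("K", 40)))
  expect_message(Dc <- poisson_distance(m), "capped")
  expect_equal(Dc["a", "b"], -log(1 - 0.95))

  m <- new_msa(c("a", "b"), c("MK--", "--VL"), check_all_gap = FALSE)
  expect_error(poisson_distance(m), "no comparable columns.*'a'.*'b'")
})

test_that("three-taxon neighbor joining solves the three-point formulas", {
  D <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3, 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tree <- neighbor_joining(D)
  # x = (dab + dac - dbc)/2 etc.
  el <- setNames(tree$edge.length[match(1:3, tree$edge[, 2])],
                 tree$tip.label)
  expect_equal(unname(el["a"]), (3 + 4 - 5) / 2)
  expect_equal(unname(el["b"]), (3 + 5 - 4) / 2)
  expect_equal(unname(el["c"]), (4 + 5 - 3) / 2)
})

test_that("neighbor joining recovers additive-matrix topologies", {
  # quartet ((a,b),(c,d)) with internal branch 2
  tr <- read_newick("((a:1,b:1.5):2,(c:0.5,d:2):1);")
  D <- ape::cophenetic.phylo(tr)[c("a", "b", "c", "d"), c("a", "b", "c", "d")]
  nj <- neighbor_joining(D)
  expect_equal(robinson_foulds(nj, ape::unroot(tr)), 0)
  # four-point condition holds for the constructed matrix
  s1 <- D["a", "b"] + D["c", "d"]
  s2 <- D["a", "c"] + D["b", "d"]
  s3 <- D["a", "d"] + D["b", "c"]
  expect_lt(s1, s2); expect_equal(s2, s3)

  expect_error(neighbor_joining(matrix(c(0, Inf, Inf, 0), 2, 2,
                                       dimnames = list(c("a", "b"), c("a", "b")))))
})

test_that("neighbor joining is consistent across 50 random additive matrices", {
  set.seed(14)
  for (i in 1:50) {
    n <- sample(4:10, 1)
    tr <- ape::rtree(n, br = function(k) stats::runif(k, 0.5, 2))
    D <- ape::cophenetic.phylo(tr)
    D <- D[sort(rownames(D)), sort(rownames(D))]
    nj <- neighbor_joining(D)
    expect_equal(robinson_foulds(nj, ape::unroot(tr)), 0, info = paste("rep", i))
  }
})

test_that("midpoint rooting targets the longest leaf-to-leaf path", {
  quart <- read_newick("((a:1,b:1):1,(c:1,d:1):1);")
  r <- midpoint_root(quart)
  expect_equal(robinson_foulds(ape::unroot(r), ape::unroot(quart)), 0)
  # symmetric quartet: root children split a|b from c|d
  kids <- phangorn::Descendants(r, length(r$tip.label) + 1, "children")
  expect_true(ape::is.monophyletic(r, c("a", "b")))

  # caterpillar with one long terminal branch: root lies on that branch
  cat_tree <- read_newick("(((a:0.1,b:0.1):0.1,c:0.1):0.1,d:10);")
  r <- midpoint_root(cat_tree)
  root_kids <- r$edge[r$edge[, 1] == length(r$tip.label) + 1, 2]
  expect_true(match("d", r$tip.label) %in% root_kids)
})

test_that("monophyly is exact leaf-descendant equality", {
  tree <- read_newick("(((a:1,b:1):1,c:1):1,(d:1,e:1):1);")
  expect_true(is_monophyletic(tree, "a"))
  expect_true(is_monophyletic(tree, c("a", "b", "c", "d", "e")))
  expect_true(is_monophyletic(tree, c("a", "b")))
  expect_true(is_monophyletic(tree, c("d", "e")))
  expect_false(is_monophyletic(tree, c("a", "c")))
  expect_false(is_monophyletic(tree, c("b", "d")))
  expect_error(is_monophyletic(tree, c("a", "zz")), "zz")
})

test_that("Robinson-Foulds counts bipartitions unique to one tree", {
  t1 <- read_newick("((a:1,b:1):1,(c:1,d:1):1,e:1);")
  expect_equal(robinson_foulds(t1, t1), 0)
  # one NNI away (exchange d and e across the cd|abe edge): the ab|cde
  # split is shared, the cd|abe vs ce|abd splits are unique -> 2
  t2 <- read_newick("((a:1,b:1):1,(c:1,e:1):1,d:1);")
  expect_equal(robinson_foulds(t1, t2), 2)
  # exchanging both cherries changes both internal splits -> 4
  t4 <- read_newick("((a:1,c:1):1,(b:1,d:1):1,e:1);")
  expect_equal(robinson_foulds(t1, t4), 4)
  t3 <- read_newick("((a:1,b:1):1,(c:1,x:1):1,e:1);")
  expect_error(robinson_foulds(t1, t3), "leaf sets differ")
})

test_that("newick i/o round-trips and flags unbalanced input", {
  txt <- "(a:1,b:1);"
  expect_equal(sort(read_newick(txt)$tip.label), c("a", "b"))
  tr <- read_newick("((a:1.25,b:0.5):0.125,(c:2,d:1):0.75);")
  back <- read_newick(write_newick(tr))
  expect_equal(robinson_foulds(tr, back), 0)
  expect_equal(sort(back$edge.length), sort(tr$edge.length))

  set.seed(15)
  for (i in 1:5) {
    tr <- ape::rtree(8)
    back <- read_newick(write_newick(tr))
    expect_equal(robinson_foulds(tr, back), 0)
    expect_equal(sort(round(back$edge.length, 6)),
                 sort(round(tr$edge.length, 6)))
  }
  expect_error(read_newick("((a:1,b:1);"), "unbalanced")
  expect_error(read_newick("(a:1,b:1));"), "offset 10")
})

test_that("zero-length simulations give a zero distance matrix", {
  tr <- read_newick("((a:0,b:0):0,(c:0,d:0):0);")
  set.seed(16)
  leaves <- evolve_protein(random_protein(80), tr, branch_scale = 1)
  msa <- new_msa(names(leaves), unname(leaves))
  expect_true(all(poisson_distance(msa) == 0))
})

test_that("planted clades are recovered as monophyletic across seeds", {
  ok <- vapply(1:20, function(seed) {
    ds <- generate_dataset(small_sim_config(seed = seed))
    msa <- progressive_align(ds$records)
    tree <- midpoint_root(neighbor_joining(poisson_distance(msa)))
    all(vapply(unique(ds$records$clade), function(cl) {
      is_monophyletic(tree, ds$records$id[ds$records$clade == cl])
    }, logical(1)))
  }, logical(1))
  expect_gte(sum(ok), 19)
})
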