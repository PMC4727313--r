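D_cda <- parse_newick("((c,d),a);")

test_that("cluster_query parses graph and set forms", {
  g <- cluster_query("(g,i);")
  expect_false(is.null(g$graph))
  expect_identical(g$leaves, c("g", "i"))
  s <- cluster_query("d, e, f")
  expect_null(s$graph)
  expect_identical(s$leaves, c("d", "e", "f"))
  expect_identical(cluster_query(c("b", "a"))$leaves, c("a", "b"))
  expect_error(cluster_query("a"), "at least 2")
  expect_error(cluster_query("a,a"), "duplicate")
  expect_error(cc_graph("a,c,d", D_cda), "graph form")
  expect_error(cc_set("a,z", D_cda), "not leaves")
})

test_that("graph contrast detects branches and nothing else", {
  expect_identical(cc_graph("(c,d);", D_cda), 1)
  expect_identical(cc_graph(D_cda, D_cda), 1)  # the whole dendrogram
  # same leaves, different internal structure: not a branch
  expect_identical(cc_graph("((a,c),d);", D_cda), 0)
  expect_identical(cc_graph("(a,d);", D_cda), 0)
})

test_that("relaxed-graph contrast is the max Jaccard over subtree partitions", {
  # reconstructed worked instance: one of three subtrees shared
  C <- cluster_query("(((b,c),a),x);")
  D <- parse_newick("((a,x),(b,c));")
  expect_equal(cc_relaxed_graph(C, D), 1 / 3)
  expect_identical(cc_set(C, D), 1)          # L(C) is D's full leaf set
  expect_identical(cc_relaxed_set(C, D), 1)
  # no shared cherry: zero
  expect_identical(
    cc_relaxed_graph("((a,b),c);", parse_newick("(((a,c),b),d);")), 0
  )
  # a branch scores exactly 1
  expect_identical(cc_relaxed_graph("(c,d);", D_cda), 1)
})

test_that("set contrasts follow the leaf-set family", {
  expect_identical(cc_set("a,c,d", D_cda), 1)
  expect_identical(cc_set("a,d", D_cda), 0)
  expect_identical(cc_set(cluster_query(D_cda$leaves), D_cda), 1)  # root set
  expect_identical(cc_relaxed_set("a,c,d", D_cda), 1)
  expect_equal(cc_relaxed_set("a,d", D_cda), 2 / 3)
})

test_that("toy-example frequencies match the step-by-step construction", {
  fit <- tie_hclust(toy_table1())
  expect_identical(cluster_frequency(fit, "(a,b);", "g"), 1)
  expect_identical(cluster_frequency(fit, "((a,b),c);", "g"), 1)
  expect_equal(cluster_frequency(fit, "(g,i);", "g"), 0.5)
  expect_equal(cluster_frequency(fit, "(h,i);", "g"), 0.5)
  expect_equal(cluster_frequency(fit, "(d,e);", "g"), 1 / 3)
  expect_equal(cluster_frequency(fit, "((d,e),f);", "g"), 1 / 3)
  # each complete dendrogram occurs once in six
  for (tr in fit$trees) {
    expect_equal(cluster_frequency(fit, tr, "g"), 1 / 6)
  }
  # a cluster crossing the separated groups never occurs as a graph
  expect_identical(cluster_frequency(fit, "((a,d),g);", "g"), 0)
  # {d,e,f} is a subtree leaf set in every dendrogram
  expect_identical(cluster_frequency(fit, "d,e,f", "s"), 1)
  expect_identical(cluster_frequency(fit, "g,h,i", "s"), 1)
  # stats::frequency dispatches on the fit
  expect_equal(frequency(fit, "(g,i);", "g"), 0.5)
})

test_that("frequency validates its inputs", {
  fit <- tie_hclust(toy_table1())
  expect_error(cluster_frequency(list(), "(a,b);", "g"), "length")
  mixed <- list(parse_newick("(a,b);"), parse_newick("(a,c);"))
  expect_error(cluster_frequency(mixed, "(a,b);", "g"), "share one leaf set")
  expect_error(cluster_frequency(fit, "a,b,c", "g"), "graph form")
  expect_error(cluster_frequency(fit, "(a,b);", "x"), "arg")
})

test_that("tie-case frequencies are F(k)/F(n), measured and analytic", {
  expect_equal(tiecase_graph_frequency(3, 2), 1 / 3)
  expect_equal(tiecase_graph_frequency(4, 2), 1 / 5)    # 3/15 by brute force
  expect_identical(tiecase_graph_frequency(5, 5), 1 / felsenstein_count(5))
  expect_error(tiecase_graph_frequency(4, 1), "in \\[2, n\\]")
  expect_error(tiecase_graph_frequency(4, 5), "in \\[2, n\\]")

  # brute-force check on 4 leaves: 3 of the 15 topologies contain cherry (a,b)
  all4 <- enumerate_all_topologies(letters[1:4])
  hits <- sum(vapply(all4, function(D) cc_graph("(a,b);", D), 0))
  expect_identical(hits / length(all4), tiecase_graph_frequency(4, 2))

  # measured over the full topology set, every cluster size, n = 3..5;
  # caterpillar query clusters (the analytic value is shape-independent)
  for (n in 3:5) {
    trees <- enumerate_all_topologies(letters[1:n])
    for (size in 2:n) {
      q <- paste0(paste(rep("(", size - 1L), collapse = ""), "a,",
                  paste(paste0(letters[2:size], ")"), collapse = ","), ";")
      expect_identical(cluster_frequency(trees, q, "g"),
                       tiecase_graph_frequency(n, size))
    }
  }
})

test_that("frequency_report is long-form, bounded and ordered across methods", {
  fit <- tie_hclust(toy_table1())
  rep <- frequency_report(list("(g,i);", "((h,i),g);", "(d,e);"), fit)
  expect_identical(nrow(rep), 12L)
  expect_true(all(rep$frequency_full >= 0 & rep$frequency_full <= 1))
  expect_true(all(rep$m == 6L))
  expect_false(any(rep$capped))
  # g and s frequencies are integer multiples of 1/m
  gs <- rep$frequency_full[rep$method %in% c("g", "s")]
  expect_true(all(abs(gs * 6 - round(gs * 6)) < 1e-12))
  # strict <= relaxed, per cluster
  for (id in unique(rep$cluster_id)) {
    r <- rep[rep$cluster_id == id, ]
    expect_lte(r$frequency_full[r$method == "g"], r$frequency_full[r$method == "rg"])
    expect_lte(r$frequency_full[r$method == "s"], r$frequency_full[r$method == "rs"])
    expect_lte(r$frequency_full[r$method == "g"], r$frequency_full[r$method == "s"])
  }
  # size-2 clusters: the cherry-detecting contrasts g, rg, s coincide
  r2 <- rep[rep$cluster_id %in% c("(g,i);", "(d,e);"), ]
  for (id in unique(r2$cluster_id)) {
    sub <- r2[r2$cluster_id == id, ]
    expect_length(unique(sub$frequency_full[sub$method %in% c("g", "rg", "s")]), 1L)
  }
  # display column honors decimals
  rep0 <- frequency_report(list("(d,e);"), fit, methods = "g", decimals = 2)
  expect_identical(rep0$frequency, 0.33)
  expect_equal(rep0$frequency_full, 1 / 3)
})

test_that("a singleton tree set gives frequency 1 to its own clusters", {
  D <- parse_newick("(((a,b),c),(d,e));")
  for (k in subtree_partition(D)) {
    q <- paste0(k, ";")
    for (meth in c("g", "rg", "s", "rs")) {
      expect_identical(cluster_frequency(list(D), q, meth), 1)
    }
  }
  expect_identical(cluster_frequency(list(D), "((a,c),b);", "g"), 0)
})
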