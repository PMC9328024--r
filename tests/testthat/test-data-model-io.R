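test_that("interaction sets drop self-loops and collapse duplicates", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c("source\ttarget", "A\tB", "A\tB", "C\tC"), f)
  expect_message(net <- read_interactions(f), "self-loop")
  expect_equal(net$edges, data.frame(from = "A", to = "B",
                                     stringsAsFactors = FALSE))
  # the node set is the union of the surviving edges' endpoints
  expect_equal(net$nodes, c("A", "B"))
})

test_that("empty edge files load as empty interaction sets", {
  f <- tempfile()
  writeLines(character(), f)
  net <- read_interactions(f)
  expect_equal(n_edges(net), 0L)
  expect_equal(n_nodes(net), 0L)
})

test_that("malformed edge lines are rejected with their line number", {
  f <- tempfile()
  writeLines(c("source\ttarget", "A\tB", "oops"), f)
  expect_error(read_interactions(f), "line 3")
})

test_that("write/read round-trips preserve the edge set in all formats", {
  nets <- list(
    empty = interaction_set(),
    single = interaction_set(data.frame(from = "A", to = "B")),
    toy = toy_networks()$type1_example,
    many = {
      set.seed(7)
      random_digraph(9, 0.3)
    }
  )
  for (net in nets) {
    for (fmt in c("edgelist", "sif", "graphml")) {
      f <- tempfile(fileext = paste0(".", fmt))
      write_interactions(net, f, format = fmt)
      back <- read_interactions(f, format = fmt)
      expect_equal(back$edges, net$edges)
      # and bit-identical on its own output
      f2 <- tempfile(fileext = paste0(".", fmt))
      write_interactions(back, f2, format = fmt)
      if (fmt != "graphml")  # graphml embeds no ordering guarantees
        expect_identical(readLines(f), readLines(f2))
    }
  }
})

test_that("expression loading validates shapes, TFs and metadata", {
  dir <- write_mini_dataset()
  ds <- read_expression(file.path(dir, "expr.tsv"),
                        file.path(dir, "meta.tsv"),
                        file.path(dir, "tf.txt"))
  expect_s3_class(ds, "expression_dataset")
  expect_equal(dim(ds$values), c(3L, 4L))
  expect_equal(sum(ds$genes$is_tf), 1L)
  expect_true(ds$genes$is_tf[ds$genes$gene_id == "G1"])
  expect_equal(table(ds$samples$condition)[["disease"]], 2L)

  # duplicated gene row names the offender
  writeLines(c("gene_id\ts1\ts2\ts3\ts4",
               "G1\t1\t2\t3\t4", "G1\t1\t2\t3\t4"),
             file.path(dir, "dup.tsv"))
  expect_error(read_expression(file.path(dir, "dup.tsv"),
                               file.path(dir, "meta.tsv"),
                               file.path(dir, "tf.txt")), "G1")

  # sample without metadata is a hard error naming it
  writeLines(c("sample_id\tcondition", "s1\tdisease", "s2\tdisease",
               "s3\tcontrol"), file.path(dir, "meta_short.tsv"))
  expect_error(read_expression(file.path(dir, "expr.tsv"),
                               file.path(dir, "meta_short.tsv"),
                               file.path(dir, "tf.txt")), "s4")
})

test_that("expression write/read round-trips", {
  sim <- simulate_regulatory_system(seed = 5, n_tf = 4, n_mrna = 8,
                                    n_samples_per_condition = 5)
  dir <- tempfile("rt")
  write_synthetic_inputs(sim, dir)
  back <- read_expression(file.path(dir, "expr.tsv"),
                          file.path(dir, "meta.tsv"),
                          file.path(dir, "tf_list.txt"))
  expect_equal(back$values, sim$dataset$values, tolerance = 1e-9)
  expect_equal(back$genes, sim$dataset$genes)
  expect_equal(back$samples, sim$dataset$samples)
  ppi <- read_interactions(file.path(dir, "ppi.tsv"))
  expect_equal(ppi$edges, sim$truth$decoy_ppi$edges)
})

test_that("sample filtering honours condition and gestational-age window", {
  vals <- matrix(rnorm(10), nrow = 2,
                 dimnames = list(c("G1", "G2"), paste0("c", 1:5)))
  ds <- expression_dataset(vals, is_tf = c(TRUE, FALSE),
                           condition = rep("control", 5),
                           gestational_age_weeks = c(30, 33, 34, 38, NA))
  term <- filter_samples(ds, "control", ga_min_weeks = 34, require_ga = TRUE)
  expect_equal(term$samples$sample_id, c("c3", "c4"))

  # identity on the condition subset when no bounds are requested
  all_ctrl <- filter_samples(ds, "control")
  expect_equal(all_ctrl$samples$sample_id, paste0("c", 1:5))
  # the input is not mutated
  expect_equal(ncol(ds$values), 5L)

  expect_error(filter_samples(ds, "disease"), "disease")
  expect_error(filter_samples(ds, "control", ga_min_weeks = 99), "no samples")
})

test_that("early/late gestational-age split partitions the age-known samples", {
  vals <- matrix(rnorm(14), nrow = 2,
                 dimnames = list(c("G1", "G2"), paste0("d", 1:7)))
  ds <- expression_dataset(vals, is_tf = c(TRUE, FALSE),
                           condition = rep("disease", 7),
                           gestational_age_weeks = c(28, 31, 33.9, 34, 36,
                                                     40, NA))
  early <- filter_samples(ds, "disease", ga_max_weeks = 34)
  late <- filter_samples(ds, "disease", ga_min_weeks = 34)
  expect_length(intersect(early$samples$sample_id,
                          late$samples$sample_id), 0L)
  known <- ds$samples$sample_id[!is.na(ds$samples$gestational_age_weeks)]
  expect_setequal(c(early$samples$sample_id, late$samples$sample_id), known)
})
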