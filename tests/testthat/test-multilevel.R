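test_that("the institution-shaped tree loads with the expected structure", {
  root <- make_institution_tree(withr::local_tempdir())
  tree <- load_tree_from_directory(root)
  expect_s3_class(tree, "attribute_tree")
  expect_identical(tree$objects, c("D", "E", "F"))
  expect_identical(tree$frame$propositions, grades5)
  expect_length(tree$root$children, 2L)
  leaves <- unlist(lapply(tree$root$children, function(ch)
    lapply(ch$children, `[[`, "name")))
  expect_identical(sort(leaves),
                   sort(c("Research_Funding", "Research_Outcomes",
                          "Teaching_Materials", "Teaching_Methods")))
  leaf1 <- tree$root$children[[1]]$children[[1]]
  expect_length(leaf1$evidence, 2L)
  expect_equal(vapply(leaf1$evidence, `[[`, 0, "weight"), c(10, 8))
})

test_that("fusing the tree yields per-node conservative results", {
  root <- make_institution_tree(withr::local_tempdir())
  tree <- load_tree_from_directory(root)
  results <- fuse_tree(tree)
  expect_length(results, 7L)           # root + 2 mid + 4 leaves
  expect_true(all(c("Objects", "Objects/Research",
                    "Objects/Research/Research_Funding") %in%
                    names(results)))
  for (mat in results) {
    expect_identical(rownames(mat), c("D", "E", "F"))
    expect_equal(unname(rowSums(mat)), rep(1, 3), tolerance = 1e-9)
    expect_true(all(mat >= -1e-12))
  }

  # leaf results equal direct er_fuse of the leaf's evidence rows
  leaf <- tree$root$children[[1]]$children[[1]]
  for (o in 1:3) {
    direct <- er_fuse(rbind(leaf$evidence[[1]]$beliefs[o, ],
                            leaf$evidence[[2]]$beliefs[o, ]),
                      weights = c(10, 8), frame = tree$frame)
    got <- results[["Objects/Research/Research_Funding"]][o, ]
    expect_equal(unname(got),
                 unname(c(direct$beliefs, direct$uncertainty)),
                 tolerance = 1e-12)
  }
})

test_that("a depth-1 tree reduces exactly to er_fuse", {
  props <- c("Cold", "Common pneumonia", "COVID-19")
  root <- make_flat_tree(withr::local_tempdir(),
                         diagnosis_dbf(), c(10, 8, 5), props)
  results <- fuse_tree(load_tree_from_directory(root))
  direct <- er_fuse(diagnosis_dbf(), c(10, 8, 5))
  expect_equal(unname(results[["Objects"]][1, ]),
               unname(c(direct$beliefs, direct$uncertainty)))
})

test_that("single object / single evidence / weight 1 is an identity chain", {
  props <- c("A", "B")
  root <- make_flat_tree(withr::local_tempdir(),
                         matrix(c(0.5, 0.3), 1, 2), weights = 1, props)
  results <- fuse_tree(load_tree_from_directory(root))
  expect_equal(unname(results[["Objects"]][1, ]), c(0.5, 0.3, 0.2),
               tolerance = 1e-12)
})

test_that("written combined files are complete, consistent and idempotent", {
  root <- make_institution_tree(withr::local_tempdir())
  tree <- load_tree_from_directory(root)
  results <- fuse_tree(tree)
  written <- write_combined_files(tree, results)
  expect_length(written, 7L)
  root_file <- file.path(root, "Objects_combined.csv")
  expect_true(root_file %in% written)
  out <- utils::read.csv(root_file, check.names = FALSE)
  expect_equal(nrow(out), 3L)
  expect_identical(names(out), c("Object", "Weight", grades5,
                                 "Uncertainty"))

  # a second full run (now reading files with Uncertainty columns)
  # reproduces identical bytes
  before <- readLines(root_file)
  tree2 <- load_tree_from_directory(root)
  write_combined_files(tree2, fuse_tree(tree2))
  expect_identical(readLines(root_file), before)

  # and the convenience wrapper agrees
  res3 <- multilevel_fuse(root)
  expect_equal(res3[["Objects"]], results[["Objects"]], tolerance = 1e-12)
})

test_that("consistent object-row permutation permutes outputs identically", {
  dir1 <- withr::local_tempdir(); dir2 <- withr::local_tempdir()
  r1 <- make_institution_tree(dir1)
  r2 <- make_institution_tree(dir2)
  # reverse object rows in every file of the second tree
  for (f in list.files(r2, pattern = "\\.csv$", recursive = TRUE,
                       full.names = TRUE)) {
    df <- utils::read.csv(f, check.names = FALSE)
    utils::write.csv(df[rev(seq_len(nrow(df))), ], f, row.names = FALSE,
                     quote = FALSE)
  }
  out1 <- fuse_tree(load_tree_from_directory(r1))[["Objects"]]
  out2 <- fuse_tree(load_tree_from_directory(r2))[["Objects"]]
  expect_equal(out1[rev(seq_len(nrow(out1))), ], out2, tolerance = 1e-12)
})

test_that("structural defects are reported with file context", {
  dir <- withr::local_tempdir()
  root <- make_institution_tree(dir)

  # mismatched proposition header in one evidence file
  bad <- file.path(root, "Research", "Research_Funding",
                   "Evidence2_Faculty.csv")
  df <- utils::read.csv(bad, check.names = FALSE)
  names(df)[3] <- "Goodish"
  utils::write.csv(df, bad, row.names = FALSE, quote = FALSE)
  err <- tryCatch(load_tree_from_directory(root), error = identity)
  expect_s3_class(err, "erfusion_validation_error")
  expect_match(conditionMessage(err), "Evidence2_Faculty.csv")
  expect_match(conditionMessage(err), "Objects_combined.csv")

  # missing combined file
  root2 <- make_institution_tree(withr::local_tempdir())
  unlink(file.path(root2, "Teaching", "Teaching_combined.csv"))
  err <- tryCatch(load_tree_from_directory(root2), error = identity)
  expect_s3_class(err, "erfusion_validation_error")
  expect_match(conditionMessage(err), "Teaching_combined.csv")

  # empty leaf folder
  root3 <- make_institution_tree(withr::local_tempdir())
  for (f in list.files(file.path(root3, "Teaching", "Teaching_Methods"),
                       pattern = "^Evidence", full.names = TRUE))
    unlink(f)
  err <- tryCatch(load_tree_from_directory(root3), error = identity)
  expect_s3_class(err, "erfusion_validation_error")
  expect_match(conditionMessage(err), "Teaching_Methods")

  expect_error(load_tree_from_directory(file.path(dir, "missing")),
               class = "erfusion_io_error")
})
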