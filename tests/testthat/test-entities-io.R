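test_that("a minimal pedigree file round-trips through the TSV dialect", {
  ped <- validate_pedigree(rbind(
    ped_row(1, "QUEEN"),
    ped_row(2, "MATE", style = "OPEN_GROUP", S = 100, D = 8),
    ped_row(3, "WORKER_GROUP", dam = 1, sire_entry = 2)))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_pedigree(ped, f)
  back <- read_pedigree(f)
  expect_equal(nrow(back), 3L)
  expect_equal(as.data.frame(back), as.data.frame(ped))
})

test_that("referential errors are reported with the offending id", {
  bad <- rbind(ped_row(1, "QUEEN"),
               ped_row(2, "MATE", style = "OPEN_GROUP", S = 10, D = 8),
               ped_row(3, "WORKER_GROUP", dam = 1, sire_entry = 99))
  expect_error(validate_pedigree(bad), "99")
  dup <- rbind(ped_row(1, "QUEEN"), ped_row(1, "QUEEN"))
  expect_error(validate_pedigree(dup), "duplicate")
  ## child precedes parent: rejected (also catches cycles)
  swapped <- rbind(ped_row(2, "QUEEN", dam = 3, sire_entry = 0),
                   ped_row(3, "QUEEN"))
  expect_error(validate_pedigree(swapped), "precede")
  wrongkind <- rbind(ped_row(1, "QUEEN"),
                     ped_row(2, "QUEEN", dam = 1, sire_entry = 1))
  expect_error(validate_pedigree(wrongkind), "MATE")
})

test_that("write/read is the identity on a simulated replicate pedigree", {
  sim <- cached_sim12()
  enc <- encode_scenario(sim, scenario_spec("I", "SS", "C_SSP"))
  f1 <- withr::local_tempfile(fileext = ".tsv")
  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_pedigree(enc$ped, f1)
  back <- read_pedigree(f1)
  write_pedigree(back, f2)
  expect_identical(readLines(f1), readLines(f2))   # canonical, idempotent
  expect_equal(as.data.frame(back), as.data.frame(validate_pedigree(enc$ped)))
  ## every worker group's queen and mate precede it; mates' parents precede
  pos <- setNames(seq_len(nrow(back)), back$id)
  wg <- back[back$kind == "WORKER_GROUP", ]
  expect_true(all(pos[as.character(wg$dam)] < pos[as.character(wg$id)]))
  expect_true(all(pos[as.character(wg$sire_entry)] < pos[as.character(wg$id)]))
})

test_that("performance records write with a header and exact line counts", {
  f <- withr::local_tempfile(fileext = ".tsv")
  empty <- data.frame(colony_id = integer(), queen_id = integer(),
                      worker_group_id = integer(), mate_entry_id = integer(),
                      year = integer(), open_group_label = character(),
                      phenotype = numeric())
  write_performance(empty, f)
  expect_length(readLines(f), 1L)                  # header only
  sim <- cached_sim12()
  enc <- encode_scenario(sim, scenario_spec("I", "SS", "C_SSP"))
  write_performance(enc$perf, f)
  expect_length(readLines(f), nrow(enc$perf) + 1L)
  back <- read_performance(f)
  expect_equal(back$phenotype, enc$perf$phenotype)
})

test_that("MatrixMarket export stores symmetric matrices as lower triangles", {
  f <- withr::local_tempfile(fileext = ".mtx")
  export_sparse(diag(2), f, symmetric = TRUE)
  header <- readLines(f, n = 1L)
  expect_match(header, "symmetric")
  body <- readLines(f)
  expect_length(body[!startsWith(body, "%")], 3L)  # dims line + 2 entries
  m <- read_sparse(f)
  expect_equal(as.matrix(m), diag(2), ignore_attr = TRUE)
  asym <- matrix(c(1, 2, 0, 1), 2)
  expect_error(export_sparse(asym, f, symmetric = TRUE), "not symmetric")
  ## inverse relationship matrix of a toy round-trips
  Ainv <- invert_factor(build_factor(toy_identified()))
  export_sparse(Ainv, f)
  expect_equal(as.matrix(read_sparse(f)), as.matrix(Ainv),
               ignore_attr = TRUE, tolerance = 1e-12)
})
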