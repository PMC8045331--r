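test_that("a slab case reproduces the analytic margin and CV", {
  cs <- slabCase()
  res <- runCase("slab", cs$gtv, cs$experts, cs$consensus,
                 directions = list(directionFromLabel("L", "intraosseous")))
  t <- caseTable(res)
  expect_identical(t$status, "ok")
  expect_equal(t$consensus_margin_mm, 7, tolerance = 1e-6)
  expect_equal(t$margin_cv, 1 / 7, tolerance = 1e-6)
  expect_identical(t$route_class, "intraosseous")
  expect_gt(t$n_vectors, 0L)
})

test_that("an identity consensus yields zero margins", {
  cs <- slabCase()
  res <- runCase("ident", cs$gtv, cs$experts, cs$gtv,
                 directions = list(directionFromLabel("L")))
  expect_equal(caseTable(res)$consensus_margin_mm, 0, tolerance = 1e-6)
})

test_that("the consensus is computed via STAPLE when not supplied", {
  cs <- slabCase()
  res <- runCase("auto", cs$gtv, cs$experts, NULL,
                 directions = list(directionFromLabel("L")))
  m <- caseTable(res)$consensus_margin_mm
  expect_gte(m, 6); expect_lte(m, 8)
  expect_error(runCase("none", cs$gtv, list(), NULL,
                       directions = list(directionFromLabel("L"))),
               class = "ctv_no_raters")
})

test_that("one unreachable direction fails alone, others succeed", {
  cs <- slabCase()
  # a barrier filling all background blocks every ray
  wall <- BinaryVolume(!occupancy(cs$gtv), voxelSpacing(cs$gtv),
                       gridOrigin(cs$gtv))
  res <- runCase("part", cs$gtv, cs$experts, cs$consensus,
                 directions = list(directionFromLabel("L")), barrier = wall)
  expect_identical(caseTable(res)$status, "failed")
  expect_match(caseTable(res)$message, "no expansion vector")
  res2 <- runCase("part2", cs$gtv, cs$experts, cs$consensus,
                  directions = list(directionFromLabel("L")))
  expect_identical(caseTable(res2)$status, "ok")
})

test_that("study summaries pool directions by route class", {
  mkResult <- function(id, margins, cvs, classes) {
    rows <- do.call(rbind, lapply(seq_along(margins), function(i)
      data.frame(case_id = id, direction_label = paste0("d", i),
                 route_class = classes[i], consensus_margin_mm = margins[i],
                 margin_cv = cvs[i], n_vectors = 100L,
                 n_rejected_interior = 0L, n_rejected_barrier = 0L,
                 n_clamped = 0L, status = "ok", message = "",
                 stringsAsFactors = FALSE)))
    new("CaseResult", caseId = id, table = rows, details = list())
  }
  r1 <- mkResult("c1", c(5, 7), c(0.5, 0.6), c("intra", "intra"))
  r2 <- mkResult("c2", c(14, 9), c(0.4, 0.3), c("intra", "extra"))
  s <- summarizeStudy(list(r1, r2))
  intra <- s[s$route_class == "intra", ]
  expect_equal(intra$median_margin_mm, 7)
  expect_equal(c(intra$min_margin_mm, intra$max_margin_mm), c(5, 14))
  expect_identical(intra$n_directions, 3L)
  expect_identical(intra$n_cases, 2L)
  extra <- s[s$route_class == "extra", ]
  expect_equal(c(extra$median_margin_mm, extra$min_margin_mm,
                 extra$max_margin_mm), c(9, 9, 9))
  expect_identical(sum(s$n_directions), 4L)
  # order invariance
  expect_identical(summarizeStudy(list(r2, r1)), s)
  # failed directions are excluded but counted
  bad <- mkResult("c3", c(99), c(0.9), "intra")
  bad@table$status <- "failed"
  s2 <- summarizeStudy(list(r1, r2, bad))
  expect_equal(s2[s2$route_class == "intra", "median_margin_mm"], 7)
  expect_identical(s2[s2$route_class == "intra", "n_failed"], 1L)
  expect_error(summarizeStudy(list(bad)), class = "ctv_nothing_to_summarize")
})

test_that("a study runs end to end from a YAML configuration", {
  dir <- tempfile("study")
  cfgPath <- writePhantomStudy(dir)
  out <- file.path(dir, "results")
  res <- runStudy(cfgPath, outDir = out, quiet = TRUE)
  expect_setequal(list.files(out),
                  c("slab.json", "box.json", "study.csv", "summary.json"))
  csv <- read.csv(file.path(out, "study.csv"), stringsAsFactors = FALSE)
  expect_identical(nrow(csv), 4L)
  expect_identical(
    names(csv)[1:9],
    c("case_id", "direction_label", "route_class", "consensus_margin_mm",
      "margin_cv", "n_vectors", "n_rejected_interior", "n_rejected_barrier",
      "n_clamped"))
  # report numbers equal the library-level results exactly
  tab <- do.call(rbind, lapply(res$results, caseTable))
  expect_equal(csv$consensus_margin_mm, tab$consensus_margin_mm,
               tolerance = 1e-12)
  expect_equal(csv$margin_cv, tab$margin_cv, tolerance = 1e-12)
  expect_equal(csv$consensus_margin_mm[csv$case_id == "slab"], 7,
               tolerance = 1e-6)
  expect_equal(csv$consensus_margin_mm[csv$direction_label == "L" &
                                         csv$case_id == "box"], 3,
               tolerance = 1e-6)
  summ <- res$summary
  expect_setequal(summ$route_class, c("intraosseous", "extraosseous"))
  unlink(dir, recursive = TRUE)
})

test_that("re-running a study produces byte-identical reports", {
  dir <- tempfile("study")
  cfgPath <- writePhantomStudy(dir)
  out1 <- file.path(dir, "r1"); out2 <- file.path(dir, "r2")
  runStudy(cfgPath, outDir = out1, quiet = TRUE)
  runStudy(cfgPath, outDir = out2, quiet = TRUE)
  for (f in list.files(out1)) {
    a <- readBin(file.path(out1, f), "raw", file.size(file.path(out1, f)))
    b <- readBin(file.path(out2, f), "raw", file.size(file.path(out2, f)))
    expect_identical(a, b)
  }
  unlink(dir, recursive = TRUE)
})

test_that("missing mask files raise an I/O error naming the path", {
  dir <- tempfile("study")
  dir.create(dir)
  cfg <- list(cases = list(list(
    case_id = "c", gtv_path = "absent.nii.gz",
    expert_ctv_paths = list(), consensus_ctv_path = "absent.nii.gz",
    directions = list(list(label = "L")))))
  cfgPath <- file.path(dir, "study.yaml")
  yaml::write_yaml(cfg, cfgPath)
  expect_error(runStudy(cfgPath, quiet = TRUE), "absent.nii.gz",
               class = "ctv_io_error")
  unlink(dir, recursive = TRUE)
})
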