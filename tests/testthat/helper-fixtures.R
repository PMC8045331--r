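# Shared study fixture: a slab case with analytic +6/+7/+8 mm experts and a
# +7 mm consensus (voxel centers at half-integers so analytic boundaries
# fall exactly between grid nodes), plus a per-axis expanded box case.

slabCase <- function() {
  n <- c(40, 6, 6)
  origin <- c(-12.5, 0.5, 0.5)
  mk <- function(hi) boxVolume(c(0, -99, -99), c(hi, 99, 99), n,
                               origin = origin)
  list(gtv = mk(10), consensus = mk(17),
       experts = list(mk(16), mk(17), mk(18)))
}

writePhantomStudy <- function(dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cs <- slabCase()
  writeMask(cs$gtv, file.path(dir, "gtv.nii.gz"))
  for (j in seq_along(cs$experts))
    writeMask(cs$experts[[j]], file.path(dir, sprintf("expert%d.nii.gz", j)))
  box <- makePhantom("box", size = list(lower = c(0, 0, 0),
                                        upper = c(10, 8, 6)),
                     expansion = list(type = "peraxis", margins = c(3, 2, 5)),
                     spacing = c(1, 1, 1))
  writeMask(gtvVolume(box), file.path(dir, "box_gtv.nii.gz"))
  writeMask(ctvVolume(box), file.path(dir, "box_ctv.nii.gz"))
  cfg <- list(cases = list(
    list(case_id = "slab",
         gtv_path = "gtv.nii.gz",
         expert_ctv_paths = as.list(sprintf("expert%d.nii.gz", 1:3)),
         directions = list(
           list(label = "L", route_class = "intraosseous"))),
    list(case_id = "box",
         gtv_path = "box_gtv.nii.gz",
         consensus_ctv_path = "box_ctv.nii.gz",
         expert_ctv_paths = list(),
         directions = list(
           list(label = "L", route_class = "intraosseous"),
           list(label = "S", route_class = "extraosseous"),
           list(label = "up45", vector = c(0, 1, 1),
                route_class = "extraosseous")))))
  cfgPath <- file.path(dir, "study.yaml")
  yaml::write_yaml(cfg, cfgPath)
  cfgPath
}
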