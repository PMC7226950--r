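#!/usr/bin/env Rscript
# 3D Zernike shape and electrostatics descriptors of the binding groove,
# compared between the two complexes.

source(file.path("analysis", "common.R"))
systems <- build_systems()

descs <- list()
for (s in systems) {
  frame <- get_frame(s$ensemble, 1)
  sel <- select_atoms(s$topology, region = "groove")
  shape <- shape_descriptor(frame, s$topology, sel, M = 64, N = 20)
  descs[[s$name]] <- shape
  el <- voxelize_electrostatics(frame, s$topology, sel, M = 64)
  dpos <- zernike_invariants(zernike_moments(el$positive, N = 20))
  write.csv(data.frame(invariant = names(unclass(shape)),
                       shape = as.numeric(shape),
                       electrostatics_pos = as.numeric(dpos)),
            file.path(RESULTS, paste0(s$name, "_zernike.csv")),
            row.names = FALSE)
}
d <- descriptor_distance(descs$wild, descs$variant)
cat(sprintf("groove shape descriptor distance (wild vs variant): %.4f\n", d))
cat(sprintf("descriptor norms: wild %.4f, variant %.4f\n",
            sqrt(sum(as.numeric(descs$wild)^2)),
            sqrt(sum(as.numeric(descs$variant)^2))))
writeLines(sprintf("%.6f", d), file.path(RESULTS, "zernike_distance.txt"))
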