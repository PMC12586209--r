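# Small, fast fixtures shared across test files. Everything is generated in
# code; caches avoid re-voxelizing/re-meshing within one file run.

.fix <- new.env(parent = emptyenv())

small_phantom_spec <- function(...) {
  args <- utils::modifyList(
    list(head_radius = 16, neck_radius = 11, neck_length = 30,
         neck_shaft_angle = 125, shaft_radius = 11, shaft_length = 50,
         cortical_thickness = 4, cortical_density = 1.1,
         trabecular_density = 0.3, voxel_spacing = 3),
    list(...))
  do.call(femur_phantom_spec, args)
}

small_phantom <- function() {
  if (is.null(.fix$vol)) .fix$vol <- generate_femur_phantom(
    small_phantom_spec(), seed = 1)
  .fix$vol
}

small_femur_mesh <- function(edge = 7) {
  key <- paste0("mesh", edge)
  if (is.null(.fix[[key]]))
    .fix[[key]] <- mesh_density_volume(small_phantom(), target_edge = edge)
  .fix[[key]]
}

# axial column with explicit drive/support sets (head drives -z)
column_mesh <- function(w = 10, h = 40, n = c(2, 2, 8)) {
  m <- box_mesh(c(w, w, h), n = n)
  top <- which(abs(m$nodes[, 3] - h) < 1e-9) - 1L
  bot <- which(abs(m$nodes[, 3]) < 1e-9) - 1L
  m$node_sets <- list(head = top, trochanter = bot)
  m
}

# cohort used by classification / stats tests
fixture_cohort <- function(seed = 11) {
  key <- paste0("coh", seed)
  if (is.null(.fix[[key]]))
    .fix[[key]] <- generate_cohort(table1_cohort_params(), seed = seed)
  .fix[[key]]
}
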