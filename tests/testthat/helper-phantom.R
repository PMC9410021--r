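# Small phantom configurations shared across tests; sizes chosen so a test
# runs in well under a second while keeping several vertebrae visible.

tiny_phantom_config <- function(seed = 1L, domain = "source", n_vertebrae = 4L,
                                shape = c(16L, 48L, 144L),
                                include_bed_artefact = FALSE, ...) {
  phantom_config(n_vertebrae = n_vertebrae, first_vertebra_id = 8L,
                 shape = shape, domain = domain,
                 include_bed_artefact = include_bed_artefact, seed = seed, ...)
}

# central sagittal slab of a phantom: ground-truth 2D labels and image
phantom_slice <- function(ph) {
  sl <- ceiling(dim(ph$dense)[1] / 2)
  list(labels = ph$dense[sl, , ],
       image = apply(ph$volume$data, c(2, 3), max),
       mask = apply(ph$spine_mask$data, c(2, 3), max))
}

phantom_weak_mask <- function(ph) {
  sl <- phantom_slice(ph)
  merge_enclosed(filter_components(build_weak_mask(sl$image, sl$mask)))
}
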