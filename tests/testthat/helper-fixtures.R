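# Small in-code fixtures shared across test files.

# One-image benthic table whose counts are the cover pattern itself.
make_benthic <- function(counts, n_images = 1) {
  do.call(rbind, lapply(seq_len(n_images), function(i) {
    data.frame(image = i, category = names(counts),
               count = as.numeric(counts))
  }))
}

empty_fish <- function() {
  data.frame(transect = c(1, 2), species = "sparisoma_viride",
             size_bin = 150, phase = "initial", count = c(0, 0))
}

empty_urchins <- function() {
  data.frame(species = character(), size_bin = numeric(),
             count = numeric())
}

# A census site from a named vector of per-image point counts.
make_site <- function(counts, site_id = "T1", sector = "southern",
                      habitat = "reef_crest", fish = empty_fish(),
                      urchins = empty_urchins(), n_images = 1) {
  site_census(site_id, sector, habitat,
              make_benthic(counts, n_images), fish, urchins,
              points_per_image = sum(counts))
}

# Compact rate table with clean hand-oracle numbers: urchin allometry
# gives 0.2 kg ind-1 y-1 at the 40-mm bin midpoint (50 mm).
make_rates <- function(...) {
  rate_table(
    calcification = c(acropora_palmata = 10.88, pseudodiploria = 9.84,
                      cca = 2.09),
    rugosity = c(acropora_palmata = 3.3309, pseudodiploria = 1.79),
    density = c(acropora_palmata = 1450, pseudodiploria = 1600),
    parrotfish = data.frame(
      species = rep("sparisoma_viride", 2),
      size_bin = c(150, 150), phase = c("initial", "terminal"),
      rate = c(60000, 120000)
    ),
    urchin_a = 0.0016, urchin_b = 3,
    ...
  )
}
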