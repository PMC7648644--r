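#!/usr/bin/env Rscript
# Step 1: generate the synthetic study world and export its input bundle.
#
# The world stands in for the four empirical inputs of the range pipeline:
# species extent-of-occurrence polygons with habitat preferences, a
# habitat-to-biome crosswalk, decadal biome maps from a toy climate, and a
# three-variant land-use reconstruction with logistic conversion arriving
# late in the tropics.

suppressPackageStartupMessages(library(habitatrange))

SEED <- 20260920L
out_dir <- "results/world"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

world <- gen_world(world_config(seed = SEED))
print(world)

# export the species polygons and the crosswalk in their interchange formats
write_geojson_polygons(world$polygons, file.path(out_dir, "species_eoo.geojson"))
xw <- world$crosswalk
xw$biomes <- vapply(xw$biomes, paste, character(1), collapse = ";")
write.csv(as.data.frame(xw), file.path(out_dir, "crosswalk.csv"),
          row.names = FALSE)
write.csv(world$mega_biomes, file.path(out_dir, "mega_biomes.csv"),
          row.names = FALSE)

# species table: group, suitability sets, extent size
areas <- world$areas
species_tab <- do.call(rbind, lapply(world$species, function(sp) data.frame(
  species_id = sp$species_id, group = sp$group,
  eoo_area_km2 = sum(sp$eoo_fraction * areas),
  suitable_biomes = paste(sp$suitable_biomes, collapse = ";"),
  suitable_artificial = paste(sp$suitable_artificial, collapse = ";"))))
write.csv(species_tab, file.path(out_dir, "species.csv"), row.names = FALSE)

# global land-use summary per variant and year
conv <- do.call(rbind, lapply(c("baseline", "lower", "upper"), function(v)
  data.frame(variant = v, year = world$landuse$years,
             converted_km2 = vapply(world$landuse$years, function(y)
               cumulative_converted_area(world$landuse, y, v, areas),
               numeric(1)))))
write.csv(conv, file.path(out_dir, "converted_area.csv"), row.names = FALSE)

# an example gridded layer in the long-CSV interchange format
write_field_csv(lu_layer(world$landuse, "cropland", 2016), world$grid,
                file.path(out_dir, "cropland_2016.csv"))

cat(sprintf("species: %d (%s)\n", length(world$species),
            paste(table(species_tab$group), collapse = "/")))
cat(sprintf("converted area 1700 -> 2016 (baseline): %.3g -> %.3g km2\n",
            conv$converted_km2[conv$variant == "baseline"][1],
            tail(conv$converted_km2[conv$variant == "baseline"], 1)))
cat(sprintf("median EOO size: %.3g km2 (tropical band hosts the small ranges)\n",
            median(species_tab$eoo_area_km2)))
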