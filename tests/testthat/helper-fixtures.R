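# Hand-built toy bundle: 2 stations, 2 source samples, 5 cultures, 6 OTUs.
# Small enough that every index can be recomputed by hand or brute force.
tiny_bundle <- function() {
  otus <- paste0("O", 1:6)
  sources <- count_table(matrix(
    c(90, 9, 1, 0, 40, 60,
      0, 50, 30, 20, 10, 90),
    nrow = 2, byrow = TRUE,
    dimnames = list(c("SRC_A", "SRC_B"), otus)))
  cultures <- count_table(matrix(
    c(30, 5, 0, 0, 15, 0,
      12, 0, 8, 0, 0, 30,
      0, 20, 0, 0, 20, 10,
      0, 0, 25, 25, 0, 0,
      5, 0, 0, 10, 0, 35),
    nrow = 5, byrow = TRUE,
    dimnames = list(paste0("C", 1:5), otus)))
  frame <- sample_frame(data.frame(
    sample_id = c("SRC_A", "SRC_B", paste0("C", 1:5)),
    kind = c("source", "source", rep("culture", 5)),
    station = c("A", "B", "A", "A", "A", "B", "B"),
    habitat = c("sediment", "water", rep("sediment", 3), "water", "water"),
    source_sample_id = c(NA, NA, "SRC_A", "SRC_A", "SRC_A", "SRC_B", "SRC_B"),
    stringsAsFactors = FALSE))
  nwk <- "((O1:1,O2:1):2,((O3:0.5,O4:0.5):1.5,(O5:1,O6:1):1):1);"
  tree <- ape::read.tree(text = nwk)
  dist <- tree_to_distances(nwk)
  fmap <- function_map(
    list(O1 = c("chemoheterotrophy"),
         O2 = c("chemoheterotrophy", "fermentation"),
         O3 = c("nitrate respiration"),
         O5 = c("fermentation"),
         O6 = c("chemoheterotrophy")),
    nesting = NULL)
  list(cultures = cultures, sources = sources, frame = frame,
       tree = tree, dist = dist, fmap = fmap)
}

# compact generated scenario for tests that need realistic structure fast
small_cfg <- function(seed, ...) {
  args <- list(n_stations = 3L, n_otus_pool = 120L,
               n_cultures_per_station = 8L, seed = seed)
  extra <- list(...)
  args[names(extra)] <- extra
  do.call(scenario_config, args)
}
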