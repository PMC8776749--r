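orders_tbl <- function() {
  dplyr::select(read_mirca_matches(), gaez_crop, removal_order)
}

# independent greedy truncation oracle: repeatedly pick the live crop with
# the smallest removal order (rainfed pool first, alphabetical ties) and
# drain it until the excess over 99% of the cell area is gone
cap_oracle <- function(areas, cell_area, orders, cap = 0.99) {
  df <- dplyr::left_join(areas, orders, by = "gaez_crop")
  excess <- sum(df$area) - cap * cell_area
  if (excess <= 0) return(list(areas = areas, removed = 0))
  removed <- 0
  repeat {
    if (excess <= 1e-15) break
    cand <- df[df$area > 0, ]
    cand_r <- cand[cand$management == "Rainfed", ]
    pool <- if (nrow(cand_r) > 0) cand_r else cand
    if (nrow(pool) == 0) break
    pool <- pool[order(pool$removal_order, pool$gaez_crop), ]
    i <- which(df$gaez_crop == pool$gaez_crop[1] &
                 df$management == pool$management[1])[1]
    take <- min(df$area[i], excess)
    df$area[i] <- df$area[i] - take
    excess <- excess - take
    removed <- removed + take
  }
  areas$area <- df$area
  list(areas = areas, removed = removed)
}
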