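# Shared fixtures: tiny hand-built entity tables and cached synthetic regions.

default_policy <- threshold_policy()

# a 3-block, 2-tract, 1-pharmacy micro-geography with hand-checkable distances
micro_fixture <- function() {
  blocks <- tibble::tibble(
    block_id = c("B1", "B2", "B3", "B4"),
    tract_id = c("T1", "T1", "T1", "T2"),
    lat = c(40.000, 40.005, 40.010, 40.500),
    lon = c(-100.000, -100.000, -100.000, -100.000),
    population = c(100L, 100L, 100L, 50L))
  tracts <- tibble::tibble(
    tract_id = c("T1", "T2"),
    state = c("WA", "WA"),
    land_area = c(0.05, 1),   # T1 density 6000 (urban), T2 density 50 (rural)
    population = c(300L, 50L),
    median_income = c(50000, 40000),
    prop_below_fpl = c(0.25, 0.10),
    car_owner_count = c(500L, 200L))
  pharmacies <- tibble::tibble(
    pharmacy_id = "P1", lat = 40.000, lon = -100.000,
    ownership = "chain", tract_id = NA_character_)
  metros <- tibble::tibble(
    metro_id = "M1", lat = 41, lon = -101, median_income = 60000)
  list(blocks = blocks, tracts = tracts, pharmacies = pharmacies,
       metros = metros)
}

# cache generated regions across tests (generation is deterministic anyway;
# this just avoids recomputation)
.region_cache <- new.env(parent = emptyenv())

cached_region <- function(key, spec, policy = threshold_policy()) {
  if (!exists(key, envir = .region_cache)) {
    assign(key, generate_region(spec, policy), envir = .region_cache)
  }
  get(key, envir = .region_cache)
}

standard_region <- function(seed = 11) {
  cached_region(paste0("std", seed),
                region_spec(n_urban = 8L, n_suburban = 8L, n_rural = 8L,
                            n_zero_pop = 1L, n_missing_income = 1L,
                            low_vehicle_fraction = 0.15, seed = seed))
}

large_region <- function() {
  cached_region("large",
                region_spec(n_urban = 50L, n_suburban = 50L, n_rural = 50L,
                            seed = 99))
}

# independent Welch / pooled t reference, written from the textbook formulas
ref_t <- function(x, y, variant = "welch") {
  nx <- length(x); ny <- length(y)
  vx <- sum((x - mean(x))^2) / (nx - 1); vy <- sum((y - mean(y))^2) / (ny - 1)
  if (variant == "welch") {
    se2 <- vx / nx + vy / ny
    stat <- (mean(x) - mean(y)) / sqrt(se2)
    df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  } else {
    sp2 <- ((nx - 1) * vx + (ny - 1) * vy) / (nx + ny - 2)
    stat <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / nx + 1 / ny))
    df <- nx + ny - 2
  }
  list(statistic = stat, df = df, p = 2 * stats::pt(-abs(stat), df))
}

# independent Pearson chi-square reference
ref_chisq <- function(m) {
  e <- outer(rowSums(m), colSums(m)) / sum(m)
  stat <- sum((m - e)^2 / e)
  df <- (nrow(m) - 1) * (ncol(m) - 1)
  list(statistic = stat, df = df, p = stats::pchisq(stat, df, lower.tail = FALSE))
}

# independent BH step-up reference
ref_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  running <- 1
  for (k in m:1) {
    running <- min(running, p[o[k]] * m / k)
    adj[o[k]] <- running
  }
  pmin(1, adj)
}
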