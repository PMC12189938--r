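#' Write / read otolith profiles as CSV
#'
#' One file per fish with columns `distance_um`, `mg_ca`, `p_ca`; the fish
#' id, edge radius and catch quarter travel in a header comment line.
#'
#' @param profile otolith_profile.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_profile_csv <- function(profile, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# fish_id=%s edge_radius=%g catch_quarter=%d",
                     profile$fish_id, profile$edge_radius,
                     profile$catch_quarter), con)
  write.csv(data.frame(distance_um = profile$distances,
                       mg_ca = profile$mg_ca, p_ca = profile$p_ca),
            con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_profile_csv
#' @export
read_profile_csv <- function(path) {
  hdr <- readLines(path, n = 1)
  kv <- regmatches(hdr, gregexpr("[a-z_]+=[^ ]+", hdr))[[1]]
  meta <- setNames(sub(".*=", "", kv), sub("=.*", "", kv))
  d <- read.csv(path, comment.char = "#")
  structure(list(fish_id = unname(meta["fish_id"]),
                 distances = d$distance_um, mg_ca = d$mg_ca, p_ca = d$p_ca,
                 edge_radius = as.numeric(meta["edge_radius"]),
                 catch_quarter = as.integer(meta["catch_quarter"]),
                 truth = NULL),
            class = "otolith_profile")
}

#' Write estimated ages as CSV
#'
#' @param results named list of `age_result` objects (names = fish ids).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_ages_csv <- function(results, path) {
  rows <- lapply(names(results), function(id) {
    r <- results[[id]]
    data.frame(fish_id = id, age = r$age, flag = r$consensus_flag,
               radii = paste(signif(r$minima_radii, 8), collapse = ";"),
               stringsAsFactors = FALSE)
  })
  write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}
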