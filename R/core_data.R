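# Shared vocabularies -------------------------------------------------------

#' Controlled vocabularies used throughout the package
#'
#' Native-status codes, growth habits, numeric wetland indicator statuses
#' (OBL = 1 ... UPL = 5), ecoregions and aggregated wetland types.
#'
#' @name vocabularies
#' @keywords internal
NULL

native_statuses <- c("NATIVE", "INTRODUCED", "ADVENTIVE", "CRYPTOGENIC",
                     "UNDETERMINED")
nonnative_statuses <- c("INTRODUCED", "ADVENTIVE", "CRYPTOGENIC")
growth_habits <- c("FORB", "GRAMINOID", "VINE", "SHRUB", "TREE")
wis_codes <- c(OBL = 1, FACW = 2, FAC = 3, FACU = 4, UPL = 5)
ecoregions <- c("CPL", "EMU", "IPL", "XER", "WMT")
wetland_types <- c("EH", "EW", "PRLH", "PRLW")

#' Is a native-status code nonnative?
#'
#' Introduced, adventive and cryptogenic taxa all count as nonnative;
#' undetermined taxa count as neither native nor nonnative (they enter
#' denominators only).
#'
#' @param status character vector of native-status codes.
#' @return logical vector.
#' @export
is_nonnative <- function(status) {
  status %in% nonnative_statuses
}

# Schemas --------------------------------------------------------------------

cover_schema <- c("site_id", "visit_no", "plot_id", "taxon_id", "cover")
traits_schema <- c("taxon_id", "native_status", "growth_habit", "wis")
sites_schema <- c("site_id", "visit_no", "x", "y", "weight", "ecoregion",
                  "wetland_type", "is_probability", "bareground")
disturbance_schema <- c("site_id", paste0("idx", 1:8))

check_schema <- function(df, expected, what) {
  missing <- setdiff(expected, names(df))
  if (length(missing) > 0) {
    stop(sprintf("%s: missing required column(s): %s", what,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  invisible(df)
}

# Dataset container ----------------------------------------------------------

#' Assemble a survey dataset from its component tables
#'
#' Bundles the plot-level cover table, the taxon trait table, the site
#' information table and (optionally) the eight-column disturbance table into
#' a single validated object used by every downstream stage.
#'
#' @param cover data.frame with columns `site_id, visit_no, plot_id, taxon_id,
#'   cover` (percent absolute cover in (0, 100]).
#' @param traits data.frame with columns `taxon_id, native_status,
#'   growth_habit, wis` (wis numeric 1-5 or NA).
#' @param sites data.frame with columns `site_id, visit_no, x, y, weight,
#'   ecoregion, wetland_type, is_probability, bareground`.
#' @param disturbance optional data.frame with columns `site_id, idx1..idx8`.
#' @param n_plots number of vegetation plots per site used as the frequency
#'   denominator (survey protocol default 5).
#' @param check if TRUE (default) hard referential/value checks are applied.
#' @return an object of class `nnpi_dataset` (a list of the four tables plus
#'   `n_plots`).
#' @export
as_dataset <- function(cover, traits, sites, disturbance = NULL,
                       n_plots = 5L, check = TRUE) {
  cover <- as.data.frame(cover)
  traits <- as.data.frame(traits)
  sites <- as.data.frame(sites)
  if (!"visit_no" %in% names(cover)) cover$visit_no <- 1L
  if (!"visit_no" %in% names(sites)) sites$visit_no <- 1L
  check_schema(cover, cover_schema, "cover")
  check_schema(traits, traits_schema, "traits")
  check_schema(sites, sites_schema, "sites")
  if (!is.null(disturbance)) {
    disturbance <- as.data.frame(disturbance)
    check_schema(disturbance, disturbance_schema, "disturbance")
  }
  if (check) {
    if (any(!is.finite(cover$cover)) ||
        any(cover$cover <= 0 | cover$cover > 100)) {
      bad <- which(!is.finite(cover$cover) | cover$cover <= 0 |
                     cover$cover > 100)
      stop(sprintf("cover: %d value(s) outside (0, 100] (first at row %d)",
                   length(bad), bad[1]), call. = FALSE)
    }
    orphan_taxa <- setdiff(unique(cover$taxon_id), traits$taxon_id)
    if (length(orphan_taxa) > 0) {
      stop(sprintf("cover references taxa with no trait row: %s",
                   paste(utils::head(orphan_taxa, 5), collapse = ", ")),
           call. = FALSE)
    }
    site_keys <- paste(sites$site_id, sites$visit_no)
    orphan_sites <- setdiff(unique(paste(cover$site_id, cover$visit_no)),
                            site_keys)
    if (length(orphan_sites) > 0) {
      stop(sprintf("cover references site-visits with no site row: %s",
                   paste(utils::head(orphan_sites, 5), collapse = ", ")),
           call. = FALSE)
    }
  }
  structure(list(cover = cover, traits = traits, sites = sites,
                 disturbance = disturbance, n_plots = as.integer(n_plots)),
            class = "nnpi_dataset")
}

#' @export
print.nnpi_dataset <- function(x, ...) {
  cat("<nnpi_dataset>\n")
  cat(sprintf("  sites:  %d site-visits (%d distinct sites)\n",
              nrow(x$sites), length(unique(x$sites$site_id))))
  cat(sprintf("  cover:  %d plot records, %d taxa (%d plots/site)\n",
              nrow(x$cover), nrow(x$traits), x$n_plots))
  cat(sprintf("  disturbance: %s\n",
              if (is.null(x$disturbance)) "absent"
              else sprintf("%d sites", nrow(x$disturbance))))
  invisible(x)
}

#' Read a survey dataset from CSV files
#'
#' @param cover_path,traits_path,sites_path,disturbance_path file paths;
#'   `disturbance_path` may be NULL.
#' @param n_plots frequency denominator (plots per site).
#' @return an `nnpi_dataset`.
#' @seealso [write_dataset()], [validate_dataset()]
#' @export
load_dataset <- function(cover_path, traits_path, sites_path,
                         disturbance_path = NULL, n_plots = 5L) {
  for (p in c(cover_path, traits_path, sites_path, disturbance_path)) {
    if (!file.exists(p)) stop(sprintf("file not found: %s", p), call. = FALSE)
  }
  read <- function(p) utils::read.csv(p, stringsAsFactors = FALSE)
  cover <- read(cover_path)
  traits <- read(traits_path)
  sites <- read(sites_path)
  disturbance <- if (!is.null(disturbance_path)) read(disturbance_path)
  if ("is_probability" %in% names(sites)) {
    sites$is_probability <- as.logical(sites$is_probability)
  }
  as_dataset(cover, traits, sites, disturbance, n_plots = n_plots)
}

#' Write a survey dataset to a directory of CSV files
#'
#' Writes `cover.csv`, `traits.csv`, `sites.csv` and (when present)
#' `disturbance.csv`. A write-then-load round trip reproduces the dataset
#' field for field.
#'
#' @param ds an `nnpi_dataset`.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_dataset <- function(ds, dir) {
  stopifnot(inherits(ds, "nnpi_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(cover = file.path(dir, "cover.csv"),
             traits = file.path(dir, "traits.csv"),
             sites = file.path(dir, "sites.csv"))
  utils::write.csv(ds$cover, paths["cover"], row.names = FALSE)
  utils::write.csv(ds$traits, paths["traits"], row.names = FALSE)
  utils::write.csv(ds$sites, paths["sites"], row.names = FALSE)
  if (!is.null(ds$disturbance)) {
    paths["disturbance"] <- file.path(dir, "disturbance.csv")
    utils::write.csv(ds$disturbance, paths["disturbance"], row.names = FALSE)
  }
  invisible(paths)
}

# Validation -----------------------------------------------------------------

issue <- function(table, id, problem) {
  data.frame(table = table, id = id, problem = problem,
             stringsAsFactors = FALSE)
}

#' Validate a dataset against the type invariants
#'
#' Reports (rather than throws) one row per violated invariant: duplicate
#' cover keys, plot ids beyond `n_plots`, out-of-vocabulary codes,
#' out-of-range wetland indicator or bareground values, non-positive weights
#' on probability sites, and revisit rows that reference no first visit.
#'
#' @param ds an `nnpi_dataset`.
#' @return a data.frame with columns `table`, `id`, `problem`; zero rows when
#'   the dataset is clean.
#' @export
validate_dataset <- function(ds) {
  stopifnot(inherits(ds, "nnpi_dataset"))
  issues <- list()
  cov <- ds$cover
  key <- paste(cov$site_id, cov$visit_no, cov$plot_id, cov$taxon_id)
  dup <- unique(key[duplicated(key)])
  for (k in dup) issues[[length(issues) + 1]] <-
    issue("cover", k, "duplicate (site, visit, plot, taxon) record")
  bad_plot <- unique(cov$site_id[cov$plot_id < 1 | cov$plot_id > ds$n_plots])
  for (s in bad_plot) issues[[length(issues) + 1]] <-
    issue("cover", s, sprintf("plot_id outside 1..%d", ds$n_plots))

  tr <- ds$traits
  for (t in tr$taxon_id[!tr$native_status %in% native_statuses])
    issues[[length(issues) + 1]] <- issue("traits", t, "unknown native_status")
  for (t in tr$taxon_id[!tr$growth_habit %in% growth_habits])
    issues[[length(issues) + 1]] <- issue("traits", t, "unknown growth_habit")
  bad_wis <- !is.na(tr$wis) & !(tr$wis %in% 1:5)
  for (t in tr$taxon_id[bad_wis])
    issues[[length(issues) + 1]] <- issue("traits", t, "wis outside 1..5")

  st <- ds$sites
  for (s in st$site_id[!st$ecoregion %in% ecoregions])
    issues[[length(issues) + 1]] <- issue("sites", s, "unknown ecoregion")
  for (s in st$site_id[!st$wetland_type %in% wetland_types])
    issues[[length(issues) + 1]] <- issue("sites", s, "unknown wetland_type")
  bad_w <- st$is_probability & (!is.finite(st$weight) | st$weight <= 0)
  for (s in st$site_id[bad_w])
    issues[[length(issues) + 1]] <-
      issue("sites", s, "probability site with non-positive weight")
  bad_bg <- !is.finite(st$bareground) | st$bareground < 0 | st$bareground > 100
  for (s in st$site_id[bad_bg])
    issues[[length(issues) + 1]] <- issue("sites", s, "bareground outside 0-100")
  v1 <- st$site_id[st$visit_no == 1]
  orphan_revisit <- st$site_id[st$visit_no > 1 & !st$site_id %in% v1]
  for (s in unique(orphan_revisit))
    issues[[length(issues) + 1]] <-
      issue("sites", s, "revisit row without a visit_no=1 row")

  if (!is.null(ds$disturbance)) {
    dd <- ds$disturbance
    neg <- apply(dd[paste0("idx", 1:8)], 1, function(r) any(r < 0, na.rm = TRUE))
    for (s in dd$site_id[neg])
      issues[[length(issues) + 1]] <-
        issue("disturbance", s, "negative sub-index value")
  }
  if (length(issues) == 0) {
    data.frame(table = character(), id = character(), problem = character(),
               stringsAsFactors = FALSE)
  } else {
    do.call(rbind, issues)
  }
}
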