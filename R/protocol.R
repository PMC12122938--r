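#' Adjacent (neighbouring-pair) measurement protocol
#'
#' Enumerates the adjacent current-injection protocol: current is driven
#' between each neighbouring electrode pair `(e, e+1)` and the voltage is
#' measured on every neighbouring pair that shares no electrode with the
#' drive pair, giving `n * (n - 3)` four-terminal patterns for `n`
#' electrodes (40 for the standard 8-electrode ring).
#'
#' Patterns are ordered by drive electrode ascending, then by measurement
#' start electrode ascending (both 1-based, wrapping modulo `n`).
#'
#' @param n_electrodes Number of electrodes on the ring (>= 4).
#' @param current_mA Injected current amplitude in mA (default 0.1).
#' @param frequency_khz Excitation frequency in kHz; carried as metadata only,
#'   the model is purely conductive (default 10).
#' @return A tibble of class `eit_protocol` with columns `pattern`,
#'   `drive_pos`, `drive_neg`, `meas_pos`, `meas_neg` and attributes
#'   `current_mA`, `frequency_khz`, `n_electrodes`.
#' @examples
#' nrow(adjacent_protocol(8)) # 40
#' @export
adjacent_protocol <- function(n_electrodes, current_mA = 0.1, frequency_khz = 10) {
  n <- as.integer(n_electrodes)
  if (is.na(n) || n < 4L) {
    stop("`n_electrodes` must be an integer >= 4 (no valid measurement pairs otherwise).",
         call. = FALSE)
  }
  wrap <- function(e) ((e - 1L) %% n) + 1L
  rows <- purrr::map_dfr(seq_len(n), function(d) {
    dp <- d; dn <- wrap(d + 1L)
    m_start <- wrap(d + seq.int(2L, n - 2L)) # measurement pairs not touching the drive
    tibble::tibble(drive_pos = dp, drive_neg = dn,
                   meas_pos = m_start, meas_neg = wrap(m_start + 1L))
  })
  rows <- dplyr::arrange(rows, .data$drive_pos, .data$meas_pos)
  out <- dplyr::mutate(rows, pattern = dplyr::row_number(), .before = 1)
  structure(out,
            class = c("eit_protocol", class(out)),
            current_mA = current_mA,
            frequency_khz = frequency_khz,
            n_electrodes = n)
}

#' Protocol metadata accessors
#' @param protocol An `eit_protocol`.
#' @return The injected current in mA / the pattern count.
#' @export
protocol_current_mA <- function(protocol) attr(protocol, "current_mA")

#' @rdname protocol_current_mA
#' @export
n_patterns <- function(protocol) nrow(protocol)

#' Write / read a protocol CSV
#'
#' Columns: `pattern_index, drive_pos, drive_neg, meas_pos, meas_neg`
#' (1-based electrode indices); current and frequency are stored as
#' commented-out header metadata by the run manifest, not in the CSV.
#'
#' @param protocol An `eit_protocol`.
#' @param path Output CSV path.
#' @return `path` invisibly; `read_protocol()` returns an `eit_protocol`.
#' @export
write_protocol <- function(protocol, path) {
  out <- dplyr::rename(tibble::as_tibble(protocol), pattern_index = "pattern")
  readr::write_csv(out, path)
  invisible(path)
}

#' @rdname write_protocol
#' @param current_mA,frequency_khz Metadata to attach on read.
#' @export
read_protocol <- function(path, current_mA = 0.1, frequency_khz = 10) {
  x <- readr::read_csv(path, show_col_types = FALSE)
  need <- c("pattern_index", "drive_pos", "drive_neg", "meas_pos", "meas_neg")
  if (!all(need %in% names(x))) {
    stop("Protocol CSV must have columns: ", paste(need, collapse = ", "), call. = FALSE)
  }
  out <- dplyr::rename(x, pattern = "pattern_index")
  n <- max(out$drive_pos, out$drive_neg, out$meas_pos, out$meas_neg)
  structure(out,
            class = c("eit_protocol", class(out)),
            current_mA = current_mA,
            frequency_khz = frequency_khz,
            n_electrodes = as.integer(n))
}
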