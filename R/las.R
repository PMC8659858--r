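# LAS 1.2 point cloud I/O (point data record format 0) and the plain CSV
# cloud dialect. The binary layout is written field-by-field with
# writeBin/readBin and interleaved via raw matrices; classification 2
# marks ground returns (ASPRS convention), everything else is read as
# non-ground.

#' Write a point cloud as LAS 1.2
#'
#' Point data record format 0 (20-byte records: scaled int32 x/y/z,
#' uint16 intensity, return byte, classification, scan angle, user data,
#' point source id). Ground points get classification 2, others 1.
#' Coordinates are stored with 1 mm scale and the cloud minimum as offset.
#'
#' @param cloud a [vk_cloud()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_las <- function(cloud, path) {
  cloud <- vk_cloud(cloud)
  n <- nrow(cloud)
  scale <- 0.001
  off <- if (n > 0) c(min(cloud$x), min(cloud$y), min(cloud$z)) else c(0, 0, 0)
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("LASF", con, nchars = 4, eos = NULL)
  writeBin(c(0L, 0L), con, size = 2, endian = "little")       # source id, encoding
  writeBin(raw(16), con)                                      # GUID
  writeBin(as.integer(c(1, 2)), con, size = 1)                # version 1.2
  writeChar(formatC("volkrig", width = 32, flag = "-"), con, nchars = 32,
            eos = NULL)                                       # system id
  writeChar(formatC("volkrig synthetic", width = 32, flag = "-"), con,
            nchars = 32, eos = NULL)                          # software
  writeBin(c(1L, 2026L), con, size = 2, endian = "little")    # day, year
  writeBin(227L, con, size = 2, endian = "little")            # header size
  writeBin(227L, con, size = 4, endian = "little")            # point offset
  writeBin(0L, con, size = 4, endian = "little")              # VLRs
  writeBin(0L, con, size = 1)                                 # format 0
  writeBin(20L, con, size = 2, endian = "little")             # record length
  writeBin(n, con, size = 4, endian = "little")
  writeBin(c(n, 0L, 0L, 0L, 0L), con, size = 4, endian = "little")
  writeBin(c(scale, scale, scale, off), con, size = 8, endian = "little")
  mm <- if (n > 0) {
    c(max(cloud$x), min(cloud$x), max(cloud$y), min(cloud$y),
      max(cloud$z), min(cloud$z))
  } else rep(0, 6)
  writeBin(mm, con, size = 8, endian = "little")
  if (n > 0) {
    to_raw <- function(v, size) writeBin(v, raw(), size = size,
                                         endian = "little")
    xyz <- matrix(to_raw(as.integer(round(rbind(
      (cloud$x - off[1]) / scale,
      (cloud$y - off[2]) / scale,
      (cloud$z - off[3]) / scale))), 4), nrow = 12)
    inten <- matrix(to_raw(as.integer(pmin(pmax(round(cloud$intensity), 0),
                                           65535)), 2), nrow = 2)
    ret <- matrix(to_raw(rep(9L, n), 1), nrow = 1)  # 1 return of 1 (bits 001 001)
    cls <- matrix(to_raw(ifelse(cloud$is_ground, 2L, 1L), 1), nrow = 1)
    zero1 <- matrix(to_raw(rep(0L, n), 1), nrow = 1)
    psid <- matrix(to_raw(rep(0L, n), 2), nrow = 2)
    rec <- rbind(xyz, inten, ret, cls, zero1, zero1, psid)
    writeBin(as.vector(rec), con)
  }
  invisible(path)
}

#' Read a LAS 1.2 point cloud
#'
#' Supports point data record formats 0 and 1; classification 2 is mapped
#' to `is_ground = TRUE`.
#'
#' @param path LAS file path.
#' @return a [vk_cloud()].
#' @export
read_las <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  sig <- readChar(con, 4, useBytes = TRUE)
  if (!identical(sig, "LASF")) stop("read_las: not a LAS file: ", path)
  invisible(readBin(con, raw(), n = 20))          # source id .. GUID
  ver <- readBin(con, integer(), n = 2, size = 1)
  invisible(readBin(con, raw(), n = 64 + 4))      # sysid, software, day/year
  invisible(readBin(con, integer(), n = 1, size = 2, endian = "little"))
  pt_offset <- readBin(con, integer(), n = 1, size = 4, endian = "little")
  invisible(readBin(con, integer(), n = 1, size = 4, endian = "little"))
  fmt <- readBin(con, integer(), n = 1, size = 1)
  reclen <- readBin(con, integer(), n = 1, size = 2, endian = "little")
  n <- readBin(con, integer(), n = 1, size = 4, endian = "little")
  invisible(readBin(con, integer(), n = 5, size = 4, endian = "little"))
  sc <- readBin(con, numeric(), n = 6, size = 8, endian = "little")
  invisible(readBin(con, numeric(), n = 6, size = 8, endian = "little"))
  if (!fmt %in% c(0L, 1L))
    stop("read_las: unsupported point format ", fmt, " (version ",
         paste(ver, collapse = "."), ")")
  seek(con, pt_offset)
  block <- readBin(con, raw(), n = as.numeric(reclen) * n)
  M <- matrix(block, nrow = reclen)
  xyz <- matrix(readBin(as.vector(M[1:12, , drop = FALSE]), integer(),
                        n = 3 * n, size = 4, endian = "little"), nrow = 3)
  inten <- readBin(as.vector(M[13:14, , drop = FALSE]), integer(),
                   n = n, size = 2, endian = "little", signed = FALSE)
  cls <- as.integer(M[16, ])
  vk_cloud(data.frame(
    x = xyz[1, ] * sc[1] + sc[4],
    y = xyz[2, ] * sc[2] + sc[5],
    z = xyz[3, ] * sc[3] + sc[6],
    intensity = inten,
    is_ground = cls == 2L))
}

#' Read / write the CSV point-cloud dialect
#'
#' Plain CSV with mandatory header `x,y,z,intensity,is_ground`
#' (`is_ground` as 0/1).
#'
#' @param cloud a [vk_cloud()].
#' @param path file path.
#' @return [write_cloud_csv()]: `path` invisibly; [read_cloud_csv()]: a
#'   [vk_cloud()].
#' @export
write_cloud_csv <- function(cloud, path) {
  cloud <- vk_cloud(cloud)
  out <- data.frame(x = cloud$x, y = cloud$y, z = cloud$z,
                    intensity = cloud$intensity,
                    is_ground = as.integer(cloud$is_ground))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_cloud_csv
#' @export
read_cloud_csv <- function(path) {
  df <- utils::read.csv(path)
  need <- c("x", "y", "z", "intensity", "is_ground")
  if (!all(need %in% names(df)))
    stop("read_cloud_csv: header must contain ", paste(need, collapse = ","))
  df$is_ground <- df$is_ground != 0
  vk_cloud(df)
}
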