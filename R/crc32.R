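# CRC-32 integrity tag.  The ubiquitous IEEE 802.3 variant: reflected
# polynomial 0xEDB88320 (i.e. 0x04C11DB7 bit-reversed), initial value and
# final XOR 0xFFFFFFFF.  The checksum is appended to the randomized payload
# stream before partitioning and verified after decoding.

#' CRC-32 checksum of a bit stream
#'
#' @param bits Integer vector of 0/1.  When `bits` is the [bytesToBits()]
#'   expansion of a byte stream the result equals the standard byte-wise
#'   CRC-32 (check value 0xCBF43926 for the ASCII bytes "123456789").
#' @return The checksum as a double holding an unsigned 32-bit value.
#' @export
#' @examples
#' sprintf("%x", crc32Bits(bytesToBits(charToRaw("123456789"))))
crc32Bits <- function(bits) {
  if (length(bits) == 0L) stop("bit stream must be nonempty")
  crc32_bits_cpp(as.integer(bits))
}

#' Append a CRC-32 tag to a bit stream
#'
#' @param bits Nonempty integer vector of 0/1.
#' @return The input followed by 32 checksum bits.
#' @seealso [crc32Check()]
#' @export
crc32Append <- function(bits) {
  c(as.integer(bits), uint32ToBits(crc32Bits(bits)))
}

#' Verify a CRC-32-tagged bit stream
#'
#' @param bits A bit stream whose final 32 bits are the checksum of the rest.
#' @return `TRUE` when the checksum matches.
#' @export
crc32Check <- function(bits) {
  if (length(bits) <= 32L) return(FALSE)
  n <- length(bits)
  stored <- bitsToUint32(bits[(n - 31L):n])
  isTRUE(crc32Bits(bits[1:(n - 32L)]) == stored)
}
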