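#include <Rcpp.h>
#include <zstd.h>
#include <vector>

using namespace Rcpp;

// [[Rcpp::export(name = ".zstd_compress")]]
RawVector zstd_compress(RawVector x, int level = 6) {
  size_t bound = ZSTD_compressBound((size_t)x.size());
  std::vector<unsigned char> buf(bound);
  size_t n = ZSTD_compress(buf.data(), bound, RAW(x), (size_t)x.size(), level);
  if (ZSTD_isError(n))
    stop("zstd compression failed: %s", ZSTD_getErrorName(n));
  RawVector out((R_xlen_t)n);
  memcpy(RAW(out), buf.data(), n);
  return out;
}

// [[Rcpp::export(name = ".zstd_decompress")]]
RawVector zstd_decompress(RawVector x, double expected_size) {
  size_t want = (size_t)expected_size;
  RawVector out((R_xlen_t)want);
  size_t n = ZSTD_decompress(RAW(out), want, RAW(x), (size_t)x.size());
  if (ZSTD_isError(n))
    stop("zstd decompression failed: %s", ZSTD_getErrorName(n));
  if (n != want)
    stop("decompressed payload length %d does not match header (%d)",
         (int)n, (int)want);
  return out;
}
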