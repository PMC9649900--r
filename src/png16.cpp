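// Minimal 16-bit grayscale PNG encoder (colour type 0, bit depth 16,
// no interlace, filter 0 on every scanline), built on zlib.  Reading is
// done through the png package, which also serves as an independent
// check of this encoder in the test suite.

#include <Rcpp.h>
#include <zlib.h>
#include <cstdio>
#include <vector>
using namespace Rcpp;

static void put_u32(std::vector<unsigned char>& v, unsigned long x) {
  v.push_back((x >> 24) & 0xff);
  v.push_back((x >> 16) & 0xff);
  v.push_back((x >> 8) & 0xff);
  v.push_back(x & 0xff);
}

static void write_chunk(FILE* f, const char type[4],
                        const unsigned char* data, size_t n) {
  unsigned char hdr[8];
  hdr[0] = (n >> 24) & 0xff; hdr[1] = (n >> 16) & 0xff;
  hdr[2] = (n >> 8) & 0xff;  hdr[3] = n & 0xff;
  std::memcpy(hdr + 4, type, 4);
  fwrite(hdr, 1, 8, f);
  if (n) fwrite(data, 1, n, f);
  uLong crc = crc32(0L, Z_NULL, 0);
  crc = crc32(crc, (const Bytef*)type, 4);
  if (n) crc = crc32(crc, data, (uInt)n);
  unsigned char tail[4] = {
    (unsigned char)((crc >> 24) & 0xff), (unsigned char)((crc >> 16) & 0xff),
    (unsigned char)((crc >> 8) & 0xff), (unsigned char)(crc & 0xff) };
  fwrite(tail, 1, 4, f);
}

// [[Rcpp::export(name = ".cpp_write_png16")]]
void cpp_write_png16(IntegerMatrix counts, std::string path) {
  int H = counts.nrow(), W = counts.ncol();
  for (int c = 0; c < W; ++c)
    for (int r = 0; r < H; ++r) {
      int v = counts(r, c);
      if (v < 0 || v > 65535)
        stop("count %d at (%d, %d) not representable as uint16", v, r + 1, c + 1);
    }

  // raw scanlines: filter byte 0 + big-endian 16-bit samples
  std::vector<unsigned char> raw((size_t)H * (1 + 2 * (size_t)W));
  size_t o = 0;
  for (int r = 0; r < H; ++r) {
    raw[o++] = 0;
    for (int c = 0; c < W; ++c) {
      unsigned v = (unsigned)counts(r, c);
      raw[o++] = (v >> 8) & 0xff;
      raw[o++] = v & 0xff;
    }
  }
  uLongf zlen = compressBound((uLong)raw.size());
  std::vector<unsigned char> z(zlen);
  if (compress2(z.data(), &zlen, raw.data(), (uLong)raw.size(), 9) != Z_OK)
    stop("zlib compression failed");

  FILE* f = std::fopen(path.c_str(), "wb");
  if (!f) stop("cannot open '%s' for writing", path.c_str());
  static const unsigned char sig[8] = {137, 80, 78, 71, 13, 10, 26, 10};
  fwrite(sig, 1, 8, f);
  std::vector<unsigned char> ihdr;
  put_u32(ihdr, (unsigned long)W);
  put_u32(ihdr, (unsigned long)H);
  ihdr.push_back(16);  // bit depth
  ihdr.push_back(0);   // grayscale
  ihdr.push_back(0); ihdr.push_back(0); ihdr.push_back(0);
  write_chunk(f, "IHDR", ihdr.data(), ihdr.size());
  write_chunk(f, "IDAT", z.data(), zlen);
  write_chunk(f, "IEND", NULL, 0);
  std::fclose(f);
}
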