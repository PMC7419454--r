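// Minimal PNG codec for 8-bit grayscale images (colour type 0, no interlace).
// Only what the package needs for phantom/mask IO; zlib does the compression.
#include <Rcpp.h>
#include <zlib.h>
#include <cstring>
#include <vector>

using namespace Rcpp;

static const unsigned char PNG_SIG[8] = {137, 80, 78, 71, 13, 10, 26, 10};

static void put_u32(std::vector<unsigned char>& v, uint32_t x) {
  v.push_back((x >> 24) & 0xff);
  v.push_back((x >> 16) & 0xff);
  v.push_back((x >> 8) & 0xff);
  v.push_back(x & 0xff);
}

static uint32_t get_u32(const unsigned char* p) {
  return ((uint32_t)p[0] << 24) | ((uint32_t)p[1] << 16) |
         ((uint32_t)p[2] << 8) | (uint32_t)p[3];
}

static void put_chunk(std::vector<unsigned char>& out, const char* type,
                      const std::vector<unsigned char>& data) {
  put_u32(out, (uint32_t)data.size());
  size_t start = out.size();
  out.insert(out.end(), type, type + 4);
  out.insert(out.end(), data.begin(), data.end());
  uint32_t crc = crc32(0L, Z_NULL, 0);
  crc = crc32(crc, out.data() + start, (uInt)(out.size() - start));
  put_u32(out, crc);
}

static int paeth(int a, int b, int c) {
  int p = a + b - c;
  int pa = std::abs(p - a), pb = std::abs(p - b), pc = std::abs(p - c);
  if (pa <= pb && pa <= pc) return a;
  if (pb <= pc) return b;
  return c;
}

// values: H x W integer matrix with entries 0..255, row r / col c in image order
// [[Rcpp::export(name = ".png_encode_gray8")]]
RawVector png_encode_gray8(IntegerMatrix values) {
  int H = values.nrow(), W = values.ncol();
  // raw scanlines, filter type 0 per row
  std::vector<unsigned char> rawdata((size_t)H * (W + 1));
  for (int r = 0; r < H; ++r) {
    rawdata[(size_t)r * (W + 1)] = 0;
    for (int c = 0; c < W; ++c) {
      int v = values(r, c);
      if (v < 0 || v > 255) stop("pixel value outside 0..255");
      rawdata[(size_t)r * (W + 1) + 1 + c] = (unsigned char)v;
    }
  }
  uLongf bound = compressBound((uLong)rawdata.size());
  std::vector<unsigned char> comp(bound);
  if (compress2(comp.data(), &bound, rawdata.data(), (uLong)rawdata.size(), 6) != Z_OK)
    stop("zlib compression failed");
  comp.resize(bound);

  std::vector<unsigned char> out(PNG_SIG, PNG_SIG + 8);
  std::vector<unsigned char> ihdr;
  put_u32(ihdr, (uint32_t)W);
  put_u32(ihdr, (uint32_t)H);
  ihdr.push_back(8);   // bit depth
  ihdr.push_back(0);   // colour type: grayscale
  ihdr.push_back(0);   // compression
  ihdr.push_back(0);   // filter
  ihdr.push_back(0);   // no interlace
  put_chunk(out, "IHDR", ihdr);
  put_chunk(out, "IDAT", comp);
  put_chunk(out, "IEND", std::vector<unsigned char>());
  return RawVector(out.begin(), out.end());
}

// [[Rcpp::export(name = ".png_decode_gray8")]]
IntegerMatrix png_decode_gray8(RawVector bytes) {
  size_t n = bytes.size();
  if (n < 8 || std::memcmp(RAW(bytes), PNG_SIG, 8) != 0)
    stop("not a PNG file");
  const unsigned char* p = RAW(bytes);
  size_t pos = 8;
  int W = -1, H = -1, depth = -1, ctype = -1, interlace = -1;
  std::vector<unsigned char> idat;
  while (pos + 8 <= n) {
    uint32_t len = get_u32(p + pos);
    if (pos + 12 + len > n) stop("truncated PNG chunk");
    const char* type = (const char*)(p + pos + 4);
    const unsigned char* data = p + pos + 8;
    if (std::memcmp(type, "IHDR", 4) == 0) {
      W = (int)get_u32(data);
      H = (int)get_u32(data + 4);
      depth = data[8];
      ctype = data[9];
      interlace = data[12];
    } else if (std::memcmp(type, "IDAT", 4) == 0) {
      idat.insert(idat.end(), data, data + len);
    } else if (std::memcmp(type, "IEND", 4) == 0) {
      break;
    }
    pos += 12 + len;
  }
  if (W <= 0 || H <= 0) stop("PNG missing IHDR");
  if (depth != 8 || ctype != 0)
    stop("unsupported PNG format: need 8-bit grayscale (got bit depth %d, colour type %d)",
         depth, ctype);
  if (interlace != 0) stop("interlaced PNG not supported");

  size_t rawlen = (size_t)H * (W + 1);
  std::vector<unsigned char> rawdata(rawlen);
  uLongf dstlen = (uLongf)rawlen;
  int zret = uncompress(rawdata.data(), &dstlen, idat.data(), (uLong)idat.size());
  if (zret != Z_OK || dstlen != rawlen) stop("PNG IDAT decompression failed");

  IntegerMatrix out(H, W);
  std::vector<unsigned char> prev(W, 0), cur(W, 0);
  for (int r = 0; r < H; ++r) {
    unsigned char filt = rawdata[(size_t)r * (W + 1)];
    const unsigned char* line = rawdata.data() + (size_t)r * (W + 1) + 1;
    for (int c = 0; c < W; ++c) {
      int x = line[c];
      int a = c > 0 ? cur[c - 1] : 0;
      int b = prev[c];
      int d = c > 0 ? prev[c - 1] : 0;
      int v;
      switch (filt) {
        case 0: v = x; break;
        case 1: v = x + a; break;
        case 2: v = x + b; break;
        case 3: v = x + (a + b) / 2; break;
        case 4: v = x + paeth(a, b, d); break;
        default: stop("unknown PNG filter type %d", (int)filt);
      }
      cur[c] = (unsigned char)(v & 0xff);
      out(r, c) = cur[c];
    }
    std::swap(prev, cur);
  }
  return out;
}
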