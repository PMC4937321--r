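# zlib and bzip2 come from the compiler's default search paths.  The xz
# (liblzma) development files may live under a different prefix than the
# compiler's sysroot (e.g. the distribution's /usr/include when R itself is
# built with a relocated toolchain); only the lzma headers are linked into a
# private include directory so the rest of that prefix cannot shadow the
# toolchain's own headers.

LZMA_PREFIX = $(firstword $(wildcard /usr/include/lzma.h) $(wildcard /usr/local/include/lzma.h))

PKG_CPPFLAGS = -Ilzma_inc
PKG_LIBS = -lz -lbz2 -L/usr/lib/x86_64-linux-gnu -L/usr/lib -llzma

$(SHLIB): lzma_inc/lzma.h

genarc.o: lzma_inc/lzma.h

lzma_inc/lzma.h:
	mkdir -p lzma_inc
	ln -sf $(LZMA_PREFIX) lzma_inc/lzma.h
	ln -sf $(dir $(LZMA_PREFIX))lzma lzma_inc/lzma

clean:
	rm -rf lzma_inc
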