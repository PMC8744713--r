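ncols 40
nrows 40
xllcorner 0
yllcorner -1200
cellsize 30
NODATA_value -9999
1 3 5 5 5 5 5 5 5 5 5 5 5 5 5 2 2 2 2 2 2 2 2 2 2 2 2 3 1 1 1 1 1 1 1 1 1 1 1 1
1 1 1 1 5 5 5 5 5 5 5 5 5 5 2 2 2 2 2 2 2 2 2 2 2 2 2 2 3 3 1 1 1 1 1 1 1 1 1 1
1 1 1 1 1 5 5 5 5 5 5 5 5 5 2 2 2 2 2 2 2 2 2 2 2 2 2 2 2 3 3 1 1 1 1 1 1 1 1 1
1 1 1 1 1 1 5 5 5 5 5 5 2 2 2 2 2 2 2 2 2 2 2 2 2 2 2 2 2 2 3 3 1 1 1 1 1 1 1 1
1 1 1 1 1 1 2 2 2 2 2 2 2 2 2 2 2 2 2 2 2 2 2 2 2 2 2 2 2 2 2 2 1 1 1 1 1 1 1 1
1 1 1 1 1 1 2 2 2 2 2 2 2 2 2 2 2 2 2 2 2 2 2 2 2 2 2 2 2 2 2 2 1 1 1 1 1 1 1 1
1 1 1 1 1 1 2 2 2 2 2 2 2 2 2 2 2 2 2 2 2 2 2 2 2 2 2 2 2 2 2 1 1 1 1 1 1 1 1 1
1 1 1 1 1 1 2 2 2 2 2 2 2 2 2 2 2 2 2 2 2 2 2 2 2 2 2 2 2 2 2 1 1 1 1 1 1 1 1 1
1 1 1 1 1 1 1 2 2 2 2 2 2 2 2 2 2 2 2 2 2 2 2 2 2 2 2 2 2 2 1 1 1 1 1 1 1 1 1 1
1 1 1 1 1 1 1 2 2 2 2 2 2 2 2 2 2 2 2 2 2 2 2 2 2 2 2 2 2 1 1 1 1 1 1 1 1 1 1 1
1 1 1 1 1 1 1 2 2 2 2 2 2 2 2 2 2 2 2 2 2 2 2 2 2 2 2 2 1 1 1 1 1 1 1 1 1 1 1 1
1 1 1 1 1 1 1 2 2 2 2 2 2 2 2 2 2 2 2 2 2 2 2 2 2 2 1 1 1 1 1 1 1 1 1 1 1 1 1 1
1 1 1 1 1 1 1 2 2 2 2 2 2 2 2 2 2 2 2 2 2 2 2 2 2 1 1 1 1 1 1 1 1 1 1 1 1 1 1 1
1 1 1 1 1 1 1 2 2 2 2 2 2 2 2 2 2 2 2 2 2 2 2 2 1 1 1 1 1 1 1 1 1 1 1 1 1 1 1 1
1 1 1 1 1 1 1 2 2 2 2 2 2 2 2 2 2 2 2 2 2 2 2 2 1 1 1 1 1 1 1 1 1 1 1 1 1 1 1 1
1 1 1 1 1 1 2 2 2 2 2 2 2 2 2 2 2 2 2 2 2 2 2 1 1 1 1 1 1 1 1 1 1 1 1 1 1 1 1 1
1 1 1 1 1 1 2 2 2 2 2 2 2 2 2 2 2 2 2 2 2 2 2 1 1 1 1 1 1 1 1 1 1 1 1 1 1 1 1 1
3 3 2 2 2 2 2 2 2 2 2 2 2 2 2 2 2 2 2 2 2 2 2 1 1 1 1 1 1 1 1 1 1 1 1 3 3 3 3 3
3 3 2 2 2 2 2 2 2 2 2 2 2 2 2 2 2 2 2 2 2 2 2 1 1 1 1 1 1 1 1 1 3 3 3 3 3 3 3 3
3 3 3 2 2 2 2 2 1 1 1 1 2 2 2 2 2 2 2 2 2 2 2 2 1 1 1 1 1 4 4 4 4 3 3 3 3 3 3 3
3 3 3 2 2 2 2 2 1 1 1 1 1 2 2 2 2 2 2 2 2 2 2 2 2 2 2 2 4 4 4 4 4 3 3 3 3 3 3 3
3 3 3 3 3 3 2 6 1 1 1 1 1 1 2 2 2 2 2 2 2 2 2 2 2 2 2 4 4 4 4 4 4 3 3 3 3 3 3 3
3 3 3 3 3 6 6 6 1 1 1 1 1 1 2 2 2 2 2 2 2 2 2 2 2 2 6 4 4 4 4 4 4 3 3 3 3 3 3 3
5 3 3 3 3 6 6 6 6 1 1 1 1 4 2 2 2 2 2 2 2 2 2 2 2 6 6 6 4 4 4 4 4 3 3 3 3 3 3 3
5 5 5 3 6 6 6 6 6 6 1 1 4 4 4 2 2 2 2 2 2 2 2 2 6 6 6 6 6 4 4 4 3 3 3 3 3 5 5 5
5 5 5 3 6 6 6 6 6 6 4 4 4 4 4 4 6 2 2 2 2 2 6 6 6 6 6 6 6 6 4 3 3 3 3 5 5 5 5 5
5 5 5 5 6 6 6 6 6 6 4 4 4 4 4 4 4 6 6 6 6 6 6 6 6 6 6 6 6 6 3 3 3 3 5 5 5 5 5 5
5 5 5 5 3 6 6 6 6 4 4 4 4 4 4 4 4 4 4 6 6 6 6 6 6 6 6 6 6 3 3 3 3 5 5 5 5 5 5 5
5 5 5 5 3 6 6 4 4 4 4 4 4 4 4 4 4 4 4 4 4 6 6 6 6 6 6 6 3 3 3 3 3 5 5 5 5 5 5 5
5 5 5 5 3 4 4 4 4 4 4 4 4 4 4 4 4 4 4 4 4 4 1 1 1 1 1 3 3 3 3 3 3 5 5 5 5 5 5 5
5 5 5 5 3 4 4 4 4 4 4 4 4 4 4 4 4 4 4 4 4 1 1 1 1 1 1 1 3 3 3 3 3 5 5 5 5 5 5 5
5 5 5 5 3 3 4 4 4 4 4 4 4 4 4 4 4 4 4 4 1 1 1 1 1 1 1 1 1 1 3 3 3 5 5 5 5 5 5 5
5 5 5 5 5 3 3 4 4 4 4 4 4 4 4 4 4 4 4 4 1 1 1 1 1 1 1 1 1 1 1 3 3 5 5 5 5 5 5 5
5 5 5 5 5 3 3 3 3 4 4 4 4 4 4 4 4 4 4 1 1 1 1 1 1 1 1 1 1 1 1 1 3 3 5 5 5 5 5 5
5 5 5 5 5 5 3 3 3 3 4 4 4 4 4 4 4 4 4 4 1 1 1 1 1 1 1 1 1 1 1 1 1 3 5 5 5 5 5 5
5 5 5 5 5 5 5 3 3 3 3 3 4 4 4 4 4 4 4 4 1 1 1 1 1 1 1 1 1 1 1 1 1 3 3 5 5 5 5 5
5 5 5 5 5 5 5 5 5 5 5 5 5 5 5 5 5 4 3 3 3 1 1 1 1 1 1 1 1 1 1 1 1 1 3 3 5 5 5 5
5 5 5 5 5 5 5 5 5 5 5 5 5 5 5 5 5 5 2 2 2 1 1 1 1 1 1 1 1 1 1 1 1 1 1 3 3 5 5 5
5 5 5 5 5 5 5 5 5 5 5 5 5 5 5 5 5 2 2 2 2 2 2 1 1 1 1 1 1 1 1 1 1 1 1 1 3 3 3 5
3 5 5 5 5 5 5 5 5 5 5 5 5 5 5 5 2 2 2 2 2 2 2 2 2 1 1 1 1 1 1 1 1 1 1 1 1 1 3 3
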