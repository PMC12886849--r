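"year","anomaly"
1880,-0.234
1881,-0.151
1882,-0.236
1883,-0.212
1884,-0.197
1885,-0.155
1886,-0.383
1887,-0.359
1888,-0.264
1889,-0.258
1890,-0.322
1891,-0.256
1892,-0.21
1893,-0.364
1894,-0.254
1895,-0.159
1896,-0.283
1897,-0.299
1898,-0.291
1899,-0.268
1900,-0.347
1901,-0.303
1902,-0.205
1903,-0.198
1904,-0.337
1905,-0.181
1906,-0.137
1907,-0.192
1908,-0.357
1909,-0.261
1910,-0.252
1911,-0.4
1912,-0.313
1913,-0.164
1914,-0.196
1915,-0.228
1916,-0.205
1917,-0.086
1918,-0.3
1919,-0.307
1920,-0.231
1921,-0.239
1922,-0.362
1923,-0.248
1924,-0.099
1925,-0.221
1926,-0.288
1927,-0.191
1928,-0.135
1929,-0.258
1930,-0.289
1931,-0.184
1932,-0.271
1933,-0.38
1934,-0.17
1935,-0.057
1936,-0.23
1937,-0.208
1938,-0.092
1939,-0.105
1940,-0.239
1941,-0.218
1942,-0.076
1943,-0.201
1944,-0.349
1945,-0.219
1946,-0.113
1947,-0.225
1948,-0.194
1949,-0.108
1950,-0.165
1951,-0.229
1952,-0.228
1953,-0.141
1954,-0.235
1955,-0.311
1956,-0.129
1957,-0.169
1958,-0.166
1959,-0.156
1960,-0.016
1961,-0.107
1962,-0.211
1963,-0.146
1964,-0.165
1965,-0.296
1966,-0.297
1967,-0.114
1968,-0.186
1969,-0.123
1970,-0.092
1971,-0.11
1972,-0.177
1973,-0.187
1974,-0.027
1975,-0.124
1976,-0.216
1977,-0.172
1978,-0.088
1979,-0.054
1980,-0.088
1981,0.057
1982,0.026
1983,-0.096
1984,-0.038
1985,0.085
1986,-0.004
1987,-0.138
1988,-0.043
1989,0.109
1990,0.096
1991,0.142
1992,0.209
1993,0.214
1994,0.131
1995,0.156
1996,0.212
1997,0.099
1998,0.078
1999,0.155
2000,0.326
2001,0.249
2002,0.344
2003,0.453
2004,0.347
2005,0.312
2006,0.352
2007,0.419
2008,0.257
2009,0.36
2010,0.597
2011,0.52
2012,0.536
2013,0.499
2014,0.681
2015,0.584
2016,0.539
2017,0.64
2018,0.632
2019,0.542
2020,0.507
2021,0.63
2022,0.673
2023,0.646
2024,0.775
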