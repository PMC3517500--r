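lon_km,lat_km,uncertainty_km,year,source
241.815804523649,166.157185218763,11.9603580969851,1910,synthetic
439.994483568007,186.349256497342,19.6664257033262,1962,synthetic
292.272169820499,88.9721443760209,16.9455022376496,1928,synthetic
387.355706768576,135.809105888475,4.93880849098787,1928,synthetic
299.860781872412,364.507509941468,6.88325932133012,1981,synthetic
418.480544651393,137.820510934107,14.0593608433846,1972,synthetic
448.773818087066,196.465586166596,22.4187950370833,1958,synthetic
126.646261346759,394.991238395451,21.0223830945324,1971,synthetic
64.3143957469147,311.767081642756,3.15091097145341,1911,synthetic
198.219227576628,245.049746925943,18.6043390771374,1934,synthetic
378.764459404629,112.448444216279,21.5238948876504,1959,synthetic
313.56711415574,141.484661966097,5.0311328144744,1948,synthetic
280.331929810345,23.404155416647,1.57832016120665,1960,synthetic
174.266928993165,203.95628554048,8.98821094888262,1902,synthetic
316.78682026919,176.086017469643,1.44433901878074,1977,synthetic
189.158242939739,273.418648444349,23.9286168187391,1919,synthetic
392.172963564517,286.806258936413,11.3645546080079,1987,synthetic
164.855677674059,350.880956661422,16.6517195873894,1958,synthetic
343.08629137231,426.654055926483,13.6068690626416,1966,synthetic
421.237517403206,224.489515536698,5.25648807524703,1997,synthetic
321.545040792553,276.495518821757,14.6195033506956,1965,synthetic
428.154882306699,262.585173676489,11.8598565051798,1921,synthetic
296.037210073555,9.99457570840605,17.753346520476,1904,synthetic
246.291858471232,188.618676506449,15.0416326418053,1900,synthetic
179.205847660778,257.085257666185,3.61704044044018,1950,synthetic
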