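run_id,encapsulation_pct,diameter_nm,nmfi
M01,60.8168178207248,71.5855191546188,1.74303549759727
M02,67.8977291510479,69.3390318658876,1.23793876446732
M03,43.4737135929921,44.470906757759,0.982967773777277
M04,72.1398838589114,38.2215727906548,1.56859723804822
M05,56.2961074997576,88.7800418403176,1.03229408114303
M06,87.8065575750222,187.179973526528,1.58138861224581
M07,63.3983828340076,57.7752704420983,1.42855481108503
M08,70.6703719558672,58.9585952410053,1.72492414242161
M09,90.2846748229269,125.255131158012,1.19548198923971
M10,41.9040184921839,17.6377893373728,1.06123202604242
M11,61.3197722948818,109.869293997196,2.17449175930832
M12,55.2627761292106,63.0866521836378,1.06014719325546
M13,85.1299818444142,124.750517099077,1.84426924468127
M14,67.2414101765208,92.1828778456103,1.54426305266049
M15,70.2615208521926,141.229614124817,1.3039101397419
MS,72.3117337208858,108.228003065108,1.87709281966105
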