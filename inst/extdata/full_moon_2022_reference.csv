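# Full-moon instants (UTC) for calendar year 2022, from standard almanac
# tabulations. Used as an independent reference for the package's own
# ephemeris (tolerance in tests: +/- 24 h).
month,instant_utc
1,2022-01-17 23:48
2,2022-02-16 16:56
3,2022-03-18 07:18
4,2022-04-16 18:55
5,2022-05-16 04:14
6,2022-06-14 11:52
7,2022-07-13 18:37
8,2022-08-12 01:36
9,2022-09-10 09:59
10,2022-10-09 20:55
11,2022-11-08 11:02
12,2022-12-08 04:08
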