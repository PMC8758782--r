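4	VIII:1	0	0	1	1
4	VIII:2	0	0	2	1
4	VIII:3	0	0	1	1
4	VIII:4	0	0	2	1
4	VIII:5	0	0	1	1
4	VIII:6	0	0	2	1
4	VIII:7	0	0	1	1
4	VIII:8	0	0	2	1
4	VIII:9	0	0	1	1
4	IX:9	VIII:1	VIII:2	1	2
4	IX:10	VIII:1	VIII:2	2	2
4	IX:12	VIII:1	VIII:2	1	2
4	IX:2	VIII:3	VIII:4	2	1
4	IX:14	VIII:5	VIII:6	1	2
4	IX:15	VIII:5	VIII:6	2	2
4	IX:16	VIII:5	VIII:6	1	2
4	IX:21	VIII:5	VIII:6	2	1
4	IX:20	VIII:7	VIII:8	2	2
4	IX:22	VIII:7	VIII:8	1	2
4	IX:1	VIII:7	VIII:8	1	1
4	IX:4	VIII:7	VIII:8	2	1
4	IX:23	0	0	2	1
4	IX:24	0	0	2	1
4	X:15	IX:22	IX:23	1	2
4	X:6	IX:9	IX:24	2	1
4	X:8	IX:9	IX:24	1	1
1	IX:25	0	0	1	1
1	IX:26	0	0	2	1
1	X:1	IX:25	IX:26	2	2
2	IX:27	0	0	1	1
2	IX:28	0	0	2	1
2	X:2	IX:27	IX:28	1	2
3	IX:29	0	0	1	1
3	IX:30	0	0	2	1
3	X:3	IX:29	IX:30	1	2
3	X:4	IX:29	IX:30	2	2
3	X:5	IX:29	IX:30	2	2
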