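snps	chrom	start_snp	end_snp	start_bp	end_bp	size_bp	contiguous
378	9	rs2479106	rs10123453	125565033	127899007	2333975	yes
337	9	rs9409287	rs7039798	128044215	129597047	1552833	yes
219	9	rs4837971	rs10986087	124289305	125482561	1193257	yes
177	9	rs1324475	rs10760198	122423730	123650357	1226628	yes
146	9	rs10760198	rs4837971	123650357	124289305	638949	yes
67	9	rs10123453	rs9409287	127899007	128044215	145209	yes
57	18	rs17240415	rs3891810	64801868	64929306	127439	no
49	21	rs8132309	rs363568	29767744	29954834	187091	no
46	4	rs17353301	rs10517306	33489284	34049422	560139	no
41	7	rs4646450	rs2246709	99104254	99203655	99402	no
40	9	rs7039798	rs10987845	129597047	129841977	244931	yes
37	1	rs6660164	rs4310401	80222072	80428702	206631	no
36	9	rs11787664	rs10118040	116821477	116919235	97759	no
35	4	rs4696998	rs7655220	21588415	21746131	157717	no
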