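patient_id,sex,birth_date,db_entry_date
P00001,F,1984-09-11,1993-06-15
P00002,M,1990-05-24,2004-02-07
P00003,F,1999-06-14,2007-10-09
P00004,F,1985-06-13,1993-01-29
P00005,M,1991-03-22,1998-07-19
P00006,M,1987-03-02,2000-05-28
P00007,F,1996-07-14,2010-06-22
P00008,M,1987-11-06,1999-12-06
P00009,F,1991-09-20,2005-06-22
P00010,M,1990-03-05,2004-11-11
P00011,M,2004-11-17,2010-05-21
P00012,F,1980-10-11,1996-02-06
P00013,M,1988-06-22,1993-06-08
P00014,M,1978-02-21,1993-08-03
P00015,F,1988-01-23,2003-08-06
P00016,M,1985-03-20,1999-05-01
P00017,M,2000-11-09,2009-04-07
P00018,M,1984-01-22,1997-08-19
P00019,M,1980-07-06,1993-08-18
P00020,F,1992-06-27,2006-03-01
P00021,M,1985-08-28,1992-08-18
P00022,M,1985-11-21,1997-01-15
P00023,M,2002-07-13,2009-07-20
P00024,F,1980-06-09,1995-08-01
P00025,M,1987-12-26,1998-07-18
P00026,F,1995-11-16,2011-06-05
P00027,F,1995-11-15,2011-01-06
P00028,M,1984-12-08,1999-02-26
P00029,M,1999-05-17,2009-01-01
P00030,M,1997-10-11,2003-07-13
P00031,F,1989-05-27,2004-08-29
P00032,M,1986-07-14,2000-05-14
P00033,M,1984-06-27,2000-09-30
P00034,M,1994-05-12,2009-04-06
P00035,M,1991-06-01,2004-07-26
P00036,M,1983-05-03,1995-03-21
P00037,F,2006-06-16,2007-04-21
P00038,F,1996-02-15,2008-10-01
P00039,M,1990-03-24,2003-06-27
P00040,F,1994-12-08,2008-12-16
P00041,M,1991-03-31,1994-05-08
P00042,F,1988-09-29,2004-01-26
P00043,F,1990-05-12,2000-11-06
P00044,F,1982-06-18,1992-04-22
P00045,F,1977-05-23,1993-08-28
P00046,M,1985-02-21,2000-04-04
P00047,M,1977-04-19,1991-01-01
P00048,F,1992-09-27,2002-06-30
P00049,F,1980-10-03,1995-07-28
P00050,F,1999-05-24,2002-08-27
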